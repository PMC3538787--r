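#' Absolute leave-one-out prediction errors
#'
#' One record per observation with the absolute difference (in days) between
#' the observed value and the (restart-mean) leave-one-out prediction, keeping
#' the primate flag for group decomposition.
#'
#' @param loo A `loo_predictions` tibble from [loo_predict()].
#' @return A tibble: `species`, `event`, `abs_error`, `is_primate`.
#' @export
absolute_errors <- function(loo) {
  out <- loo |>
    tibble::as_tibble() |>
    dplyr::mutate(abs_error = abs(.data$pc_day - .data$pred)) |>
    dplyr::select("species", "event", "abs_error", "is_primate")
  attr(out, "model") <- attr(loo, "model")
  out
}

#' Count observations whose error exceeds a threshold
#'
#' Strict exceedance (`abs_error > theta`), split into primate and non-primate
#' contributions; the two always sum to the total.
#'
#' @param errors A tibble from [absolute_errors()].
#' @param theta Threshold in days, `>= 0`.
#' @return A one-row tibble: `theta`, `n_total`, `n_primate`, `n_nonprimate`.
#' @export
count_exceeding <- function(errors, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta >= 0)
  exceed <- errors$abs_error > theta
  tibble::tibble(
    theta = theta,
    n_total = sum(exceed),
    n_primate = sum(exceed & errors$is_primate),
    n_nonprimate = sum(exceed & !errors$is_primate)
  )
}

#' Exceedance-count profile over a threshold grid
#'
#' Evaluates [count_exceeding()] at every threshold of an ascending grid and
#' records which `(species, event)` cells exceed each one. Counts are
#' non-increasing in the threshold and partition exactly into primate and
#' non-primate parts.
#'
#' @param errors A tibble from [absolute_errors()].
#' @param theta_grid Ascending numeric thresholds in days (default `1:30`).
#' @return An `error_profile` tibble (`theta`, `n_total`, `n_primate`,
#'   `n_nonprimate`) carrying the per-threshold exceedance sets and the full
#'   observation key set as attributes.
#' @export
error_profile <- function(errors, theta_grid = 1:30) {
  if (is.unsorted(theta_grid, strictly = FALSE)) {
    abort("theta_grid must be sorted ascending", class = "devtiming_value_error")
  }
  counts <- purrr::map_dfr(theta_grid, \(th) count_exceeding(errors, th))
  keys <- paste(errors$species, errors$event, sep = "\r")
  sets <- purrr::map(theta_grid, \(th) keys[errors$abs_error > th])
  names(sets) <- format(theta_grid, trim = TRUE)
  structure(counts, class = c("error_profile", class(counts)),
            exceed_sets = sets, all_keys = sort(keys),
            model = attr(errors, "model"))
}

#' Events flagged as large-error by two models simultaneously
#'
#' Intersects the exceedance sets of two profiles at a common threshold. Both
#' profiles must have been computed on the same observations and contain
#' `theta` in their grids.
#'
#' @param profile_a,profile_b `error_profile` objects.
#' @param theta A threshold present in both grids.
#' @return A list with `events` (tibble of `species`, `event`) and `count`.
#' @export
profile_overlap <- function(profile_a, profile_b, theta) {
  if (!identical(attr(profile_a, "all_keys"), attr(profile_b, "all_keys"))) {
    abort("profiles were not computed on the same observation set",
          class = "devtiming_value_error")
  }
  key <- format(theta, trim = TRUE)
  sa <- attr(profile_a, "exceed_sets")
  sb <- attr(profile_b, "exceed_sets")
  if (!key %in% names(sa) || !key %in% names(sb)) {
    abort(sprintf("theta = %s is not on both profiles' grids", key),
          class = "devtiming_value_error")
  }
  common <- intersect(sa[[key]], sb[[key]])
  parts <- strsplit(common, "\r", fixed = TRUE)
  list(
    events = tibble::tibble(
      species = purrr::map_chr(parts, 1, .default = NA_character_),
      event = purrr::map_chr(parts, 2, .default = NA_character_)
    ),
    count = length(common)
  )
}

#' @rdname error_profile
#' @param object An `error_profile`.
#' @param ... Unused.
#' @export
autoplot.error_profile <- function(object, ...) {
  d <- object |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(c("n_total", "n_primate", "n_nonprimate"),
                        names_to = "group", values_to = "n") |>
    dplyr::mutate(group = dplyr::recode(.data$group, n_total = "all species",
                                        n_primate = "primates",
                                        n_nonprimate = "non-primates"))
  ggplot2::ggplot(d, ggplot2::aes(.data$theta, .data$n,
                                  linetype = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "threshold θ (days)",
                  y = "events with |error| > θ",
                  linetype = NULL,
                  title = attr(object, "model"))
}
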