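#' Fit the offset-log dummy regression at a fixed offset
#'
#' Fits `ln(pc_day - k) = X beta` by least squares on the regression design
#' configuration (base levels dropped, primate x cortical / primate x limbic
#' interactions, intercept). The offset `k` absorbs early organizational
#' development (implantation, blastulation, germ-layer differentiation) assumed
#' shared across species; the historical fixed value is `k = 7` days, while
#' [estimate_k()] chooses it from data. Solved via QR factorization, never by
#' inverting the normal equations.
#'
#' @param df An event-table tibble.
#' @param k Offset in days, `0 <= k < min(pc_day)`.
#' @param base_species,base_event Base levels (`NULL` = lexicographically first).
#' @param interactions,intercept Design options, see [build_design()].
#' @return An `fd_fit` object with elements `k`, `beta` (named by design
#'   column), `design`, `fitted_log`, `residuals_log` and the training data.
#' @export
fit_fd_given_k <- function(df, k, base_species = NULL, base_event = NULL,
                           interactions = TRUE, intercept = TRUE) {
  df <- canonical_order(validate_event_table(df))
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k >= min(df$pc_day)) {
    abort(sprintf(
      "offset k must satisfy 0 <= k < min(pc_day) = %.4g (got %s)",
      min(df$pc_day), format(k)), class = "devtiming_domain_error")
  }
  design <- build_design(df, drop_base = TRUE, base_species = base_species,
                         base_event = base_event, interactions = interactions,
                         intercept = intercept)
  qr_x <- qr(design$matrix)
  check_full_rank(qr_x, design$column_labels)
  y <- log(df$pc_day - k)
  beta <- qr.coef(qr_x, y)
  fitted_log <- drop(design$matrix %*% beta)
  structure(
    list(
      k = k,
      k_estimated = FALSE,
      beta = setNames(beta, design$column_labels),
      design = design,
      fitted_log = fitted_log,
      residuals_log = y - fitted_log,
      data = df,
      correlation_profile = NULL
    ),
    class = "fd_fit"
  )
}

check_full_rank <- function(qr_x, labels) {
  p <- length(labels)
  if (qr_x$rank < p) {
    bad <- labels[qr_x$pivot[(qr_x$rank + 1):p]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")),
          class = "devtiming_rank_error")
  }
}

#' Estimate the offset by correlation maximization
#'
#' Evaluates a uniform grid of `grid_points` offsets over
#' `[delta, min(pc_day) - delta]`; for each, fits the offset-log regression and
#' computes the Pearson correlation between observed days and back-transformed
#' in-sample predictions `exp(fitted) + k`. Returns the grid maximizer (ties
#' broken toward smaller `k`), optionally sharpened by a Brent search within
#' one grid step of the winner (`refine = TRUE`), which matters in the
#' near-noiseless regime where the grid rarely contains the generative offset.
#'
#' @inheritParams fit_fd_given_k
#' @param grid_points Number of grid points (default 200).
#' @param scale Correlation scale: `"day"` (default; observed vs
#'   back-transformed days) or `"log"` (log-days vs fitted).
#' @param refine Refine the grid winner by Brent search in its bracketing
#'   interval?
#' @param delta Guard band away from 0 and from `min(pc_day)`, in days.
#' @return A list with `k_star`, `correlation` (at `k_star`),
#'   `correlation_profile` (tibble over the grid: `k`, `correlation`) and
#'   `grid_step`.
#' @export
estimate_k <- function(df, grid_points = 200, scale = c("day", "log"),
                       refine = TRUE, delta = 0.01, base_species = NULL,
                       base_event = NULL, interactions = TRUE,
                       intercept = TRUE) {
  scale <- match.arg(scale)
  df <- canonical_order(validate_event_table(df))
  if (nrow(df) < 3) {
    abort("estimate_k needs at least 3 observations",
          class = "devtiming_value_error")
  }
  design <- build_design(df, drop_base = TRUE, base_species = base_species,
                         base_event = base_event, interactions = interactions,
                         intercept = intercept)
  qr_x <- qr(design$matrix)
  check_full_rank(qr_x, design$column_labels)
  k_max <- min(df$pc_day)
  if (k_max <= 2 * delta) {
    abort("min(pc_day) too small to bracket an offset grid",
          class = "devtiming_domain_error")
  }
  pc <- df$pc_day
  if (stats::sd(pc) == 0) {
    abort("degenerate correlation: observed values have zero variance",
          class = "devtiming_value_error")
  }
  cor_at <- function(k) {
    y <- log(pc - k)
    fitted <- drop(design$matrix %*% qr.coef(qr_x, y))
    if (scale == "day") {
      pred <- exp(fitted) + k
      if (stats::sd(pred) == 0) return(NA_real_)
      cor(pc, pred)
    } else {
      if (stats::sd(fitted) == 0) return(NA_real_)
      cor(y, fitted)
    }
  }
  grid <- seq(delta, k_max - delta, length.out = grid_points)
  profile <- vapply(grid, cor_at, numeric(1))
  if (all(is.na(profile))) {
    abort("degenerate correlation: zero prediction variance on entire grid",
          class = "devtiming_value_error")
  }
  i_star <- which.max(profile)  # first max -> smallest k on ties
  k_star <- grid[i_star]
  corr_star <- profile[i_star]
  step <- if (grid_points > 1) grid[2] - grid[1] else k_max - 2 * delta
  if (refine && grid_points > 1) {
    lo <- max(delta, k_star - step)
    hi <- min(k_max - delta, k_star + step)
    opt <- optimize(cor_at, interval = c(lo, hi), maximum = TRUE,
                    tol = .Machine$double.eps^0.5)
    if (!is.na(opt$objective) && opt$objective >= corr_star) {
      k_star <- opt$maximum
      corr_star <- opt$objective
    }
  }
  list(
    k_star = k_star,
    correlation = corr_star,
    correlation_profile = tibble::tibble(k = grid, correlation = profile),
    grid_step = step
  )
}

#' Fit the offset-log dummy regression, estimating the offset from data
#'
#' Convenience wrapper: estimates `k` by [estimate_k()] (unless a fixed `k` is
#' supplied, e.g. `k = 7` for the historical model variant), then fits the
#' regression at that offset.
#'
#' @inheritParams estimate_k
#' @param k Fixed offset in days, or `NULL` (default) to estimate it.
#' @return An `fd_fit`; when `k` was estimated, `correlation_profile` holds the
#'   grid profile.
#' @examples
#' tab <- generate_events(synthetic_spec(n_species = 5, n_events = 8,
#'                                       seed = 1))$table
#' fit <- fit_fd(tab)
#' glance(fit)
#' @export
fit_fd <- function(df, k = NULL, grid_points = 200, scale = c("day", "log"),
                   refine = TRUE, base_species = NULL, base_event = NULL,
                   interactions = TRUE, intercept = TRUE) {
  scale <- match.arg(scale)
  profile <- NULL
  estimated <- is.null(k)
  if (estimated) {
    est <- estimate_k(df, grid_points = grid_points, scale = scale,
                      refine = refine, base_species = base_species,
                      base_event = base_event, interactions = interactions,
                      intercept = intercept)
    k <- est$k_star
    profile <- est$correlation_profile
  }
  fit <- fit_fd_given_k(df, k, base_species = base_species,
                        base_event = base_event, interactions = interactions,
                        intercept = intercept)
  fit$k_estimated <- estimated
  fit$correlation_profile <- profile
  fit
}

#' Predict post-conceptional days from a fitted offset-log regression
#'
#' Returns `exp(x . beta) + k` for each `(species, event)` query; always
#' strictly greater than `k`.
#'
#' @param object An `fd_fit`.
#' @param newdata Data frame with `species` and `event` columns; defaults to
#'   the training observations.
#' @param ... Unused.
#' @return Numeric vector of predicted days, aligned to `newdata` rows.
#' @export
predict.fd_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(exp(object$fitted_log) + object$k)
  X <- encode_query(object$design, newdata$species, newdata$event)
  unname(drop(exp(X %*% object$beta))) + object$k
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf(
    "<fd_fit> offset-log dummy regression: %d obs, %d coefficients\n",
    nrow(x$data), length(x$beta)))
  cat(sprintf("  k = %.4f days (%s)\n", x$k,
              if (x$k_estimated) "estimated" else "fixed"))
  cat(sprintf("  residual SD (log scale) = %.4f\n", stats::sd(x$residuals_log)))
  invisible(x)
}

#' @rdname fit_fd
#' @param x An `fd_fit`.
#' @export
tidy.fd_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @rdname fit_fd
#' @export
glance.fd_fit <- function(x, ...) {
  y <- log(x$data$pc_day - x$k)
  pred_day <- exp(x$fitted_log) + x$k
  tibble::tibble(
    k = x$k,
    k_estimated = x$k_estimated,
    n = nrow(x$data),
    n_params = length(x$beta) + as.integer(x$k_estimated),
    r_squared_log = 1 - sum(x$residuals_log^2) / sum((y - mean(y))^2),
    sigma_log = stats::sd(x$residuals_log),
    correlation_day = cor(x$data$pc_day, pred_day)
  )
}

#' @rdname fit_fd
#' @param object An `fd_fit`.
#' @export
autoplot.fd_fit <- function(object, ...) {
  d <- tibble::tibble(
    observed = object$data$pc_day,
    fitted = exp(object$fitted_log) + object$k,
    is_primate = object$data$is_primate
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$fitted,
                                  colour = .data$is_primate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observed PC day", y = "fitted PC day",
                  colour = "primate")
}

#' Complete a sparse species-by-event table with model predictions
#'
#' Emits every cell of the species x event grid spanned by the training data,
#' keeping observed values (`source = "observed"`) and filling the rest with
#' model predictions (`source = "predicted"`).
#'
#' @param fit An `fd_fit` or `ffnn_fit`.
#' @param only_missing Return only the predicted (previously unknown) cells?
#' @return A tibble in the event-table schema plus a `source` column.
#' @export
complete_table <- function(fit, only_missing = FALSE) {
  df <- fit$data
  design <- fit$design
  grid <- tidyr::expand_grid(species = design$species_levels,
                             event = design$event_levels)
  grid$is_primate <- unname(design$primate_map[grid$species])
  grid$event_class <- unname(design$class_map[grid$event])
  out <- grid |>
    dplyr::left_join(df[c("species", "event", "pc_day")],
                     by = c("species", "event")) |>
    dplyr::mutate(source = ifelse(is.na(.data$pc_day), "predicted", "observed"))
  miss <- is.na(out$pc_day)
  if (any(miss)) {
    out$pc_day[miss] <- predict(fit, out[miss, c("species", "event")])
  }
  out <- out[c("species", "event", "pc_day", "is_primate", "event_class",
               "source")]
  if (only_missing) out <- dplyr::filter(out, .data$source == "predicted")
  out
}
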