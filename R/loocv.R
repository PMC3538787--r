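#' Leave-one-out predictions for either model
#'
#' For each known observation, refits the chosen model on the remaining
#' observations and predicts the held-out cell on the original day scale.
#' For the offset-log regression, the offset `k` is re-estimated inside every
#' training fold so the held-out value never informs it. For the network, each
#' fold is trained from `restarts` independent initializations; per-realization
#' predictions are retained (list-column `pred_all`) and averaged into `pred`.
#' Realization seeds are derived from `(seed, species, event, restart)`, so
#' results are invariant to observation order.
#'
#' The input must pass [filter_min_coverage()], which guarantees every held-out
#' observation's species and event stay represented in its training fold.
#'
#' @param df An event-table tibble satisfying the coverage constraints.
#' @param model `"fd"` (offset-log regression) or `"ffnn"` (network).
#' @param hidden,skip,decay Network architecture (ignored for `"fd"`).
#' @param restarts Network restarts per fold (ignored for `"fd"`).
#' @param seed Master seed for network initializations.
#' @param k Fixed offset for `"fd"` (`NULL` = re-estimate per fold).
#' @param grid_points,scale,refine Offset-estimation controls, see
#'   [estimate_k()].
#' @param max_iter,tol Network optimizer controls.
#' @return A `loo_predictions` tibble: `species`, `event`, `pc_day` (observed),
#'   `pred` (days; restart mean for the network), `is_primate`, `event_class`,
#'   and for the network a `pred_all` list-column of per-realization days.
#' @export
loo_predict <- function(df, model = c("fd", "ffnn"), hidden = 1, skip = FALSE,
                        decay = 0.05, restarts = 10, seed = 1, k = NULL,
                        grid_points = 200, scale = "day", refine = TRUE,
                        max_iter = 2000, tol = 1e-8) {
  model <- match.arg(model)
  df <- validate_event_table(df)
  check_loo_feasible(df)
  out <- if (model == "fd") {
    loo_fd(df, k = k, grid_points = grid_points, scale = scale, refine = refine)
  } else {
    loo_ffnn(df, hidden = hidden, skip = skip, decay = decay,
             restarts = restarts, seed = seed, max_iter = max_iter, tol = tol)
  }
  config <- list(model = model,
                 hidden = hidden, skip = skip, decay = decay,
                 restarts = restarts, seed = seed, k = k)
  structure(out, class = c("loo_predictions", class(out)),
            model = model, config = config)
}

check_loo_feasible <- function(df) {
  ev <- dplyr::count(df, .data$event)
  sp <- dplyr::count(df, .data$species)
  if (any(ev$n < 2) || any(sp$n < 2)) {
    abort(paste("leave-one-out needs every event in >= 2 species and every",
                "species with >= 2 events; run filter_min_coverage() first"),
          class = "devtiming_value_error")
  }
}

loo_fd <- function(df, k = NULL, grid_points = 200, scale = "day",
                   refine = TRUE) {
  n <- nrow(df)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    train <- df[-i, ]
    fit <- fit_fd(train, k = k, grid_points = grid_points, scale = scale,
                  refine = refine)
    pred[i] <- predict(fit, df[i, c("species", "event")])
  }
  df |>
    dplyr::mutate(pred = pred) |>
    dplyr::select("species", "event", "pc_day", "pred", "is_primate",
                  "event_class")
}

loo_ffnn <- function(df, hidden, skip, decay, restarts, seed, max_iter, tol) {
  n <- nrow(df)
  arch <- ffnn_arch(hidden, skip, decay)
  pred_all <- vector("list", n)
  for (i in seq_len(n)) {
    train <- canonical_order(df[-i, ])
    design <- build_design(train, drop_base = FALSE, interactions = FALSE,
                           intercept = FALSE)
    y <- log(train$pc_day)
    x_q <- encode_query(design, df$species[i], df$event[i])
    pred_all[[i]] <- vapply(seq_len(restarts), function(r) {
      p <- train_ffnn(design$matrix, y, arch,
                      seed = derive_seed(seed, df$species[i], df$event[i], r),
                      max_iter = max_iter, tol = tol)
      exp(ffnn_forward(p, x_q))
    }, numeric(1))
  }
  df |>
    dplyr::mutate(pred = purrr::map_dbl(pred_all, mean),
                  pred_all = pred_all) |>
    dplyr::select("species", "event", "pc_day", "pred", "pred_all",
                  "is_primate", "event_class")
}

#' Mean squared prediction error on the day scale
#'
#' The cross-validation criterion: predictions are back-transformed to days
#' before comparison, and the mean of squared differences is returned.
#'
#' @param observed,predicted Equal-length numeric vectors of days.
#' @return A single nonnegative number (days squared).
#' @export
prediction_error <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("observed and predicted must have equal length",
          class = "devtiming_shape_error")
  }
  if (length(observed) == 0) {
    abort("prediction_error needs at least one observation",
          class = "devtiming_value_error")
  }
  mean((observed - predicted)^2)
}

#' @export
autoplot.loo_predictions <- function(object, log_scale = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$pc_day, .data$pred,
                                            colour = .data$is_primate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed PC day", y = "LOO-predicted PC day",
                  colour = "primate",
                  title = sprintf("leave-one-out predictions (%s)",
                                  attr(object, "model")))
  if (log_scale) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

default_lambda_grid <- function() c(0, 10^seq(-3, 0, length.out = 21))

#' Hyperparameter grid search by leave-one-out error
#'
#' Evaluates the network's leave-one-out mean squared error over a grid of
#' hidden-unit counts and decay values. For each cell the error is computed per
#' realization (restart) and averaged (`average = "errors"`, the default); the
#' alternative `"predictions"` first averages predictions across restarts and
#' scores the mean. The chosen cell minimizes the averaged error, ties broken
#' toward smaller `h`, then smaller `lambda`.
#'
#' @param df An event-table tibble passing the coverage filter.
#' @param h_grid Integer vector of hidden-unit counts (default `1:5`).
#' @param lambda_grid Decay values (default: 0 plus 21 points log-spaced on
#'   `[1e-3, 1]`).
#' @param skip Include the skip layer in every candidate?
#' @param restarts Restarts per fold (default 10).
#' @param seed Master seed.
#' @param average `"errors"` or `"predictions"` (see Details).
#' @param max_iter,tol Optimizer controls.
#' @return An `error_grid`: tibble with columns `h`, `lambda`, `error`
#'   (restart-averaged day-scale MSE), `error_sd` (across restarts), plus
#'   attributes `h_star`, `lambda_star`.
#' @export
grid_search <- function(df, h_grid = 1:5, lambda_grid = default_lambda_grid(),
                        skip = FALSE, restarts = 10, seed = 1,
                        average = c("errors", "predictions"),
                        max_iter = 2000, tol = 1e-8) {
  average <- match.arg(average)
  if (length(h_grid) == 0 || length(lambda_grid) == 0) {
    abort("h_grid and lambda_grid must be nonempty",
          class = "devtiming_value_error")
  }
  df <- validate_event_table(df)
  check_loo_feasible(df)
  grid <- tidyr::expand_grid(h = sort(as.integer(h_grid)),
                             lambda = sort(lambda_grid))
  res <- purrr::pmap(grid, function(h, lambda) {
    loo <- loo_predict(df, model = "ffnn", hidden = h, skip = skip,
                       decay = lambda, restarts = restarts, seed = seed,
                       max_iter = max_iter, tol = tol)
    per_realization <- vapply(seq_len(restarts), function(r) {
      prediction_error(loo$pc_day, purrr::map_dbl(loo$pred_all, r))
    }, numeric(1))
    err <- if (average == "errors") {
      mean(per_realization)
    } else {
      prediction_error(loo$pc_day, loo$pred)
    }
    c(error = err, error_sd = stats::sd(per_realization))
  })
  grid$error <- purrr::map_dbl(res, "error")
  grid$error_sd <- purrr::map_dbl(res, "error_sd")
  best <- which.min(grid$error)  # grid sorted by (h, lambda): first min wins ties
  structure(grid, class = c("error_grid", class(grid)),
            h_star = grid$h[best], lambda_star = grid$lambda[best],
            restarts = restarts, average = average, seed = seed)
}

#' @export
print.error_grid <- function(x, ...) {
  cat(sprintf("<error_grid> %d cells (restarts=%d, averaged over %s)\n",
              nrow(x), attr(x, "restarts"), attr(x, "average")))
  cat(sprintf("  chosen: h = %d, lambda = %g (LOO MSE = %.6g)\n",
              attr(x, "h_star"), attr(x, "lambda_star"),
              min(x$error)))
  NextMethod()
}

#' @rdname grid_search
#' @param x,object An `error_grid`.
#' @param ... Unused.
#' @export
glance.error_grid <- function(x, ...) {
  tibble::tibble(
    h_star = attr(x, "h_star"),
    lambda_star = attr(x, "lambda_star"),
    min_error = min(x$error),
    n_cells = nrow(x),
    restarts = attr(x, "restarts")
  )
}

#' @rdname grid_search
#' @export
autoplot.error_grid <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object), h = factor(.data$h))
  ggplot2::ggplot(d, ggplot2::aes(.data$lambda, .data$error,
                                  colour = .data$h, group = .data$h)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("point", x = attr(object, "lambda_star"),
                      y = min(object$error), shape = 1, size = 4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "weight decay λ", y = "LOO mean squared error (days²)",
                  colour = "hidden units")
}
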