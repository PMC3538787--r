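#' Network architecture descriptor
#'
#' A single-hidden-layer feed-forward network with logistic hidden units,
#' linear output, optional skip (direct input-to-output) connections and a
#' weight-decay penalty. With the hidden contribution silenced, the skip layer
#' alone is an ordinary linear regression.
#'
#' @param hidden Number of hidden units `h >= 1`.
#' @param skip Include direct linear input-to-output weights?
#' @param decay Weight-decay coefficient `lambda >= 0` multiplying the sum of
#'   squared parameters (biases included) in the training loss.
#' @return An `ffnn_arch` list.
#' @export
ffnn_arch <- function(hidden = 1, skip = FALSE, decay = 0) {
  stopifnot(hidden >= 1, decay >= 0)
  structure(list(hidden = as.integer(hidden), skip = isTRUE(skip),
                 decay = decay), class = "ffnn_arch")
}

#' Total free-parameter count of the network
#'
#' `h * (n_inputs + 1)` input-to-hidden weights and hidden biases, `h + 1`
#' hidden-to-output weights and output bias, plus `n_inputs` skip weights if
#' present. For the 105-input encoding of 10 species + 95 events, a one-unit
#' skip-free network has 108 parameters.
#'
#' @param n_inputs Number of input units (`s + e` binary indicators).
#' @param hidden Hidden units `h >= 1`.
#' @param skip Skip layer present?
#' @return Integer parameter count.
#' @export
count_params <- function(n_inputs, hidden, skip = FALSE) {
  stopifnot(hidden >= 1, n_inputs >= 1)
  as.integer(hidden * (n_inputs + 1) + (hidden + 1) +
               if (isTRUE(skip)) n_inputs else 0)
}

# theta layout: [W (h x d, column-major), b (h), v (h), b0, u (d if skip)]
unpack_theta <- function(theta, d, h, skip) {
  i <- 0
  W <- matrix(theta[seq_len(h * d)], h, d)
  i <- h * d
  b <- theta[i + seq_len(h)]; i <- i + h
  v <- theta[i + seq_len(h)]; i <- i + h
  b0 <- theta[i + 1]; i <- i + 1
  u <- if (skip) theta[i + seq_len(d)] else NULL
  list(W = W, b = b, v = v, b0 = b0, u = u)
}

make_params <- function(theta, arch, n_inputs, labels = NULL) {
  p <- unpack_theta(theta, n_inputs, arch$hidden, arch$skip)
  structure(
    list(arch = arch, n_inputs = n_inputs, theta = theta,
         input_to_hidden_weights = p$W, hidden_biases = p$b,
         hidden_to_output_weights = p$v, output_bias = p$b0,
         skip_weights = p$u, column_labels = labels),
    class = "ffnn_params"
  )
}

#' Forward pass of the network
#'
#' `output = b0 + sum_h v_h * logistic(b_h + w_h . x) (+ u . x if skip)`,
#' vectorized over the rows of `rows`.
#'
#' @param params An `ffnn_params` object (e.g. from [train_ffnn()]).
#' @param rows Numeric matrix, one query per row, width `n_inputs`.
#' @return Numeric vector of outputs (log-day scale).
#' @export
ffnn_forward <- function(params, rows) {
  stopifnot(inherits(params, "ffnn_params"))
  rows <- as.matrix(rows)
  if (ncol(rows) != params$n_inputs) {
    abort(sprintf("row width %d does not match n_inputs %d",
                  ncol(rows), params$n_inputs),
          class = "devtiming_shape_error")
  }
  H <- plogis(sweep(rows %*% t(params$input_to_hidden_weights), 2,
                    params$hidden_biases, "+"))
  out <- params$output_bias + drop(H %*% params$hidden_to_output_weights)
  if (params$arch$skip) out <- out + drop(rows %*% params$skip_weights)
  out
}

#' Weight-decay-penalized training loss
#'
#' Sum of squared errors of the forward pass against log-scale targets, plus
#' `lambda` times the sum of squares of all parameters (biases included).
#'
#' @param params An `ffnn_params`.
#' @param rows Input matrix.
#' @param targets Log-scale response vector, one per row.
#' @param lambda Decay coefficient; defaults to the architecture's.
#' @return A single nonnegative number.
#' @export
penalized_loss <- function(params, rows, targets, lambda = params$arch$decay) {
  if (nrow(as.matrix(rows)) != length(targets)) {
    abort("rows and targets are not aligned", class = "devtiming_shape_error")
  }
  e <- ffnn_forward(params, rows) - targets
  sum(e^2) + lambda * sum(params$theta^2)
}

# Loss and analytic gradient on the packed parameter vector.
ffnn_objective <- function(theta, X, y, h, skip, lambda) {
  d <- ncol(X)
  p <- unpack_theta(theta, d, h, skip)
  Z <- sweep(X %*% t(p$W), 2, p$b, "+")
  H <- plogis(Z)
  pred <- p$b0 + drop(H %*% p$v)
  if (skip) pred <- pred + drop(X %*% p$u)
  e <- pred - y
  list(value = sum(e^2) + lambda * sum(theta^2),
       e = e, H = H, p = p)
}

ffnn_gradient <- function(theta, X, y, h, skip, lambda) {
  d <- ncol(X)
  o <- ffnn_objective(theta, X, y, h, skip, lambda)
  e <- o$e; H <- o$H; p <- o$p
  dv <- drop(2 * crossprod(H, e))
  db0 <- 2 * sum(e)
  dZ <- (2 * e %o% p$v) * H * (1 - H)      # n x h
  dW <- crossprod(dZ, X)                   # h x d
  db <- colSums(dZ)
  du <- if (skip) drop(2 * crossprod(X, e)) else NULL
  c(as.vector(dW), db, dv, db0, du) + 2 * lambda * theta
}

#' Train the network by penalized least squares
#'
#' Weights are initialized uniformly in `[-0.5, 0.5]` from `seed` and the
#' penalized sum of squares is minimized by full-batch BFGS with the analytic
#' gradient. Deterministic given `(data, arch, seed)`. Non-convergence within
#' `max_iter` iterations is recorded on the fit (field `converged`), with the
#' best parameters found returned.
#'
#' @param rows Binary input matrix (rows = observations).
#' @param targets Log-scale responses.
#' @param arch An [ffnn_arch()].
#' @param seed Integer seed for the initial weights.
#' @param max_iter Maximum BFGS iterations.
#' @param tol Relative convergence tolerance.
#' @param labels Optional column labels stored with the parameters.
#' @return An `ffnn_params` with extra fields `value` (final penalized loss),
#'   `converged`, `seed`.
#' @export
train_ffnn <- function(rows, targets, arch, seed = 1, max_iter = 2000,
                       tol = 1e-8, labels = NULL) {
  stopifnot(inherits(arch, "ffnn_arch"))
  X <- as.matrix(rows)
  if (nrow(X) < 2) abort("need at least 2 rows", class = "devtiming_value_error")
  if (nrow(X) != length(targets)) {
    abort("rows and targets are not aligned", class = "devtiming_shape_error")
  }
  d <- ncol(X)
  np <- count_params(d, arch$hidden, arch$skip)
  theta0 <- with_private_seed(seed, runif(np, -0.5, 0.5))
  res <- optim(
    theta0,
    fn = function(th) ffnn_objective(th, X, targets, arch$hidden, arch$skip,
                                     arch$decay)$value,
    gr = function(th) ffnn_gradient(th, X, targets, arch$hidden, arch$skip,
                                    arch$decay),
    method = "BFGS",
    control = list(maxit = max_iter, reltol = tol)
  )
  params <- make_params(res$par, arch, d, labels)
  params$value <- res$value
  params$converged <- res$convergence == 0
  params$seed <- as.integer(seed)
  params
}

#' Fit the feed-forward network to an event table
#'
#' Builds the all-indicator design (`s + e` binary inputs, no base dropping,
#' no intercept column), takes `ln(pc_day)` as the response, and trains
#' `restarts` networks from independent random initializations, keeping the
#' one with the lowest penalized loss. Restart seeds are derived from `seed`.
#'
#' @param df An event-table tibble.
#' @param hidden,skip,decay Architecture, see [ffnn_arch()]. The default
#'   `hidden = 1`, `skip = FALSE`, `decay = 0.05` is the complexity-matched
#'   architecture whose parameter count is comparable to the offset-log
#'   regression's.
#' @param restarts Number of random restarts (default 10).
#' @param seed Master seed.
#' @param max_iter,tol Optimizer controls, see [train_ffnn()].
#' @return An `ffnn_fit`: best `params`, per-restart losses, the design, data.
#' @examples
#' tab <- generate_events(synthetic_spec(n_species = 5, n_events = 8,
#'                                       seed = 1))$table
#' fit <- fit_ffnn(tab, restarts = 2, seed = 1)
#' glance(fit)
#' @export
fit_ffnn <- function(df, hidden = 1, skip = FALSE, decay = 0.05, restarts = 10,
                     seed = 1, max_iter = 2000, tol = 1e-8) {
  df <- canonical_order(validate_event_table(df))
  arch <- ffnn_arch(hidden, skip, decay)
  design <- build_design(df, drop_base = FALSE, interactions = FALSE,
                         intercept = FALSE)
  y <- log(df$pc_day)
  fits <- purrr::map(seq_len(restarts), function(r) {
    train_ffnn(design$matrix, y, arch,
               seed = derive_seed(seed, "fit", r),
               max_iter = max_iter, tol = tol,
               labels = design$column_labels)
  })
  losses <- purrr::map_dbl(fits, "value")
  best <- fits[[which.min(losses)]]
  structure(
    list(params = best, restart_losses = losses, arch = arch,
         design = design, data = df, seed = as.integer(seed)),
    class = "ffnn_fit"
  )
}

#' Predict post-conceptional days from a fitted network
#'
#' Back-transforms the log-scale network output with `exp` (no offset), so
#' predictions are always strictly positive.
#'
#' @param object An `ffnn_fit`.
#' @param newdata Data frame with `species` and `event`; defaults to training
#'   observations.
#' @param ... Unused.
#' @return Numeric vector of predicted days.
#' @export
predict.ffnn_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) {
    object$design$matrix
  } else {
    encode_query(object$design, newdata$species, newdata$event)
  }
  exp(ffnn_forward(object$params, X))
}

#' @export
print.ffnn_fit <- function(x, ...) {
  cat(sprintf(
    "<ffnn_fit> h=%d skip=%s decay=%g: %d obs, %d parameters, %d restart(s)\n",
    x$arch$hidden, x$arch$skip, x$arch$decay, nrow(x$data),
    length(x$params$theta), length(x$restart_losses)))
  cat(sprintf("  best penalized loss = %.6g (converged: %s)\n",
              x$params$value, x$params$converged))
  invisible(x)
}

#' @rdname fit_ffnn
#' @param x An `ffnn_fit`.
#' @param ... Unused.
#' @export
tidy.ffnn_fit <- function(x, ...) {
  p <- x$params
  labs <- p$column_labels %||% paste0("input", seq_len(p$n_inputs))
  h <- p$arch$hidden
  rows <- list(
    tidyr::expand_grid(unit = seq_len(h), input = labs) |>
      dplyr::mutate(term = sprintf("hidden%d<-%s", .data$unit, .data$input),
                    estimate = as.vector(t(p$input_to_hidden_weights))) |>
      dplyr::select("term", "estimate"),
    tibble::tibble(term = sprintf("hidden%d<-bias", seq_len(h)),
                   estimate = p$hidden_biases),
    tibble::tibble(term = sprintf("output<-hidden%d", seq_len(h)),
                   estimate = p$hidden_to_output_weights),
    tibble::tibble(term = "output<-bias", estimate = p$output_bias)
  )
  if (p$arch$skip) {
    rows <- c(rows, list(tibble::tibble(term = paste0("skip<-", labs),
                                        estimate = p$skip_weights)))
  }
  dplyr::bind_rows(rows)
}

#' @rdname fit_ffnn
#' @export
glance.ffnn_fit <- function(x, ...) {
  e <- log(x$data$pc_day) - ffnn_forward(x$params, x$design$matrix)
  tibble::tibble(
    hidden = x$arch$hidden,
    skip = x$arch$skip,
    decay = x$arch$decay,
    n = nrow(x$data),
    n_params = length(x$params$theta),
    sse_log = sum(e^2),
    penalized_loss = x$params$value,
    restarts = length(x$restart_losses),
    converged = x$params$converged
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
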