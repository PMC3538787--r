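test_that("parameter counting matches the architecture identity", {
  expect_identical(count_params(105, 1, skip = FALSE), 108L)
  expect_identical(count_params(105, 1, skip = TRUE), 213L)
  expect_identical(count_params(2, 1, skip = FALSE), 5L)
  # property over random tuples
  withr::with_seed(4, {
    for (i in 1:25) {
      d <- sample(1:200, 1); h <- sample(1:6, 1); s <- sample(c(TRUE, FALSE), 1)
      expect_identical(count_params(d, h, s),
                       as.integer(h * (d + 1) + h + 1 + if (s) d else 0))
    }
  })
})

random_params <- function(d, h, skip, decay = 0, seed = 1) {
  arch <- ffnn_arch(h, skip, decay)
  theta <- withr::with_seed(seed, runif(count_params(d, h, skip), -1, 1))
  devtiming:::make_params(theta, arch, d)
}

test_that("the forward pass matches a scalar-loop oracle", {
  # zero weights: output is the output bias for any row
  p <- random_params(4, 2, skip = TRUE)
  p$theta[] <- 0
  p <- devtiming:::make_params(p$theta, p$arch, 4)
  p$output_bias <- 3.25
  p$theta[length(p$theta) - 4] <- 3.25  # keep packed vector in step
  expect_equal(ffnn_forward(p, diag(4)), rep(3.25, 4))

  # h = 1, v = 2, zero inputs to the hidden unit: 2 * logistic(0) = 1
  arch <- ffnn_arch(1, skip = FALSE)
  theta <- c(0, 0, 0, 2, 0)  # W (1x2), b, v, b0
  p1 <- devtiming:::make_params(theta, arch, 2)
  expect_equal(ffnn_forward(p1, matrix(0, 1, 2)), 1.0)

  # random weights vs an explicit double loop
  withr::with_seed(11, {
    X <- matrix(rbinom(6 * 7, 1, 0.5), 6, 7)
  })
  p <- random_params(7, 3, skip = TRUE, seed = 8)
  oracle <- vapply(seq_len(nrow(X)), function(i) {
    acc <- p$output_bias
    for (hh in 1:3) {
      z <- p$hidden_biases[hh]
      for (j in 1:7) z <- z + p$input_to_hidden_weights[hh, j] * X[i, j]
      acc <- acc + p$hidden_to_output_weights[hh] * (1 / (1 + exp(-z)))
    }
    for (j in 1:7) acc <- acc + p$skip_weights[j] * X[i, j]
    acc
  }, numeric(1))
  expect_equal(ffnn_forward(p, X), oracle, tolerance = 1e-12)

  expect_error(ffnn_forward(p, matrix(0, 2, 5)),
               class = "devtiming_shape_error")
})

test_that("the penalized loss reduces to SSE at zero decay", {
  p <- random_params(5, 2, skip = FALSE, seed = 3)
  withr::with_seed(5, X <- matrix(rbinom(20 * 5, 1, 0.5), 20, 5))
  t_perfect <- ffnn_forward(p, X)
  expect_equal(penalized_loss(p, X, t_perfect, lambda = 0), 0)
  y <- t_perfect + 1
  expect_equal(penalized_loss(p, X, y, lambda = 0), sum((1)^2 * rep(1, 20)))
  expect_equal(penalized_loss(p, X, y, lambda = 0.3),
               20 + 0.3 * sum(p$theta^2))
})

test_that("the analytic gradient matches central finite differences", {
  withr::with_seed(21, {
    X <- matrix(rbinom(15 * 6, 1, 0.5), 15, 6)
    y <- rnorm(15)
  })
  for (cfg in list(c(h = 1, skip = TRUE), c(h = 3, skip = FALSE))) {
    h <- cfg[["h"]]; skip <- as.logical(cfg[["skip"]])
    lambda <- 0.07
    np <- count_params(6, h, skip)
    theta <- withr::with_seed(22, runif(np, -1, 1))
    g <- devtiming:::ffnn_gradient(theta, X, y, h, skip, lambda)
    fn <- function(th) devtiming:::ffnn_objective(th, X, y, h, skip, lambda)$value
    eps <- 1e-6
    g_num <- vapply(seq_len(np), function(i) {
      e <- numeric(np); e[i] <- eps
      (fn(theta + e) - fn(theta - e)) / (2 * eps)
    }, numeric(1))
    expect_equal(g, g_num, tolerance = 1e-5)
  }
})

test_that("training is deterministic and fits realizable targets", {
  sim <- dense_sim(n_species = 4, n_events = 5, noise_sd = 0.05, seed = 6)
  design <- build_design(sim$table, drop_base = FALSE, interactions = FALSE,
                         intercept = FALSE)
  y <- log(sim$table$pc_day)

  # a linear map is exactly representable through the skip layer
  withr::with_seed(13, beta <- runif(ncol(design$matrix), -1, 1))
  y_lin <- drop(design$matrix %*% beta)
  fit <- train_ffnn(design$matrix, y_lin, ffnn_arch(1, skip = TRUE, decay = 1e-6),
                    seed = 42)
  sse <- sum((ffnn_forward(fit, design$matrix) - y_lin)^2)
  expect_lt(sse, 1e-6)

  # determinism: same seed, bitwise-identical parameters
  a <- train_ffnn(design$matrix, y, ffnn_arch(1, decay = 0.05), seed = 7)
  b <- train_ffnn(design$matrix, y, ffnn_arch(1, decay = 0.05), seed = 7)
  expect_identical(a$theta, b$theta)
  c_ <- train_ffnn(design$matrix, y, ffnn_arch(1, decay = 0.05), seed = 8)
  expect_false(identical(a$theta, c_$theta))

  # trained optimum beats 100 random parameter draws
  arch <- ffnn_arch(1, decay = 0.05)
  trained <- train_ffnn(design$matrix, y, arch, seed = 1)
  np <- count_params(ncol(design$matrix), 1, FALSE)
  rand_losses <- withr::with_seed(99, vapply(1:100, function(i) {
    p <- devtiming:::make_params(runif(np, -0.5, 0.5), arch, ncol(design$matrix))
    penalized_loss(p, design$matrix, y, lambda = 0.05)
  }, numeric(1)))
  expect_lte(trained$value, min(rand_losses))
})

test_that("with the hidden path silenced the skip layer is ordinary regression", {
  sim <- dense_sim(n_species = 4, n_events = 6, noise_sd = 0.1, seed = 10)
  # full-rank inputs (base levels dropped) so the OLS comparison is exact
  design <- build_design(sim$table, drop_base = TRUE, interactions = FALSE,
                         intercept = FALSE)
  X <- design$matrix
  y <- log(sim$table$pc_day)
  ols <- stats::lm.fit(cbind(1, X), y)
  arch <- ffnn_arch(1, skip = TRUE, decay = 0)
  theta <- numeric(count_params(ncol(X), 1, TRUE))
  p <- devtiming:::make_params(theta, arch, ncol(X))
  p$output_bias <- ols$coefficients[1]
  p$skip_weights <- ols$coefficients[-1]
  # re-pack so forward() sees the manual weights
  p$theta <- c(as.vector(p$input_to_hidden_weights), p$hidden_biases,
               p$hidden_to_output_weights, p$output_bias, p$skip_weights)
  expect_equal(ffnn_forward(p, X), unname(ols$fitted.values), tolerance = 1e-10)

  # trained with skip and no decay on noiseless linear data: matches OLS fit
  y_lin <- drop(cbind(1, X) %*% ols$coefficients)
  fit <- train_ffnn(X, y_lin, arch, seed = 5)
  expect_equal(ffnn_forward(fit, X), y_lin, tolerance = 1e-5)
})

test_that("stronger decay never reduces the fitted SSE", {
  sim <- dense_sim(n_species = 4, n_events = 5, noise_sd = 0.2, seed = 12)
  design <- build_design(sim$table, drop_base = FALSE, interactions = FALSE,
                         intercept = FALSE)
  y <- log(sim$table$pc_day)
  sse_at <- vapply(c(0, 0.01, 0.05, 0.1), function(lam) {
    best <- min(vapply(1:3, function(r) {
      f <- train_ffnn(design$matrix, y, ffnn_arch(1, decay = lam),
                      seed = 100 + r)
      sum((ffnn_forward(f, design$matrix) - y)^2)
    }, numeric(1)))
    best
  }, numeric(1))
  expect_true(all(diff(sse_at) >= -1e-8))
})

test_that("table-level fit predicts positive days and round-trips JSON", {
  sim <- dense_sim(n_species = 4, n_events = 5, noise_sd = 0.1, seed = 14)
  fit <- fit_ffnn(sim$table, restarts = 3, seed = 2)
  expect_length(fit$restart_losses, 3)
  expect_equal(fit$params$value, min(fit$restart_losses))
  q <- tidyr::expand_grid(species = unique(sim$table$species),
                          event = unique(sim$table$event))
  expect_true(all(predict(fit, q) > 0))
  gl <- glance(fit)
  expect_equal(gl$n_params, count_params(4 + 5, 1, FALSE))
  expect_equal(nrow(tidy(fit)), gl$n_params)

  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(predict(back, q), predict(fit, q), tolerance = 1e-12)

  # a zero forward output maps to exactly one day
  p0 <- fit$params
  p0$theta[] <- 0
  p0 <- devtiming:::make_params(p0$theta, p0$arch, p0$n_inputs)
  expect_equal(exp(ffnn_forward(p0, matrix(0, 1, p0$n_inputs))), 1.0)
})

test_that("training quality is competitive with the reference optimizer", {
  sim <- dense_sim(n_species = 5, n_events = 6, noise_sd = 0.15, seed = 16)
  design <- build_design(sim$table, drop_base = FALSE, interactions = FALSE,
                         intercept = FALSE)
  y <- log(sim$table$pc_day)
  lam <- 0.05
  ours <- min(vapply(1:5, function(r) {
    train_ffnn(design$matrix, y, ffnn_arch(1, decay = lam), seed = r)$value
  }, numeric(1)))
  theirs <- min(vapply(1:5, function(r) {
    withr::with_seed(r, {
      f <- nnet::nnet(design$matrix, y, size = 1, linout = TRUE, decay = lam,
                      maxit = 2000, trace = FALSE)
    })
    sum(f$residuals^2) + lam * sum(f$wts^2)
  }, numeric(1)))
  expect_lte(ours, theirs * 1.001)
})
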