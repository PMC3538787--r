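test_that("noiseless generative tables are interpolated exactly at the true offset", {
  sim <- dense_sim(n_species = 4, n_events = 5, k_true = 5, noise_sd = 0)
  fit <- fit_fd_given_k(sim$table, k = 5)
  expect_lt(max(abs(fit$residuals_log)), 1e-8)
  # back-transform identity on observed values
  x <- sim$table$pc_day
  expect_equal(exp(log(x - 5)) + 5, x, tolerance = 1e-14)
})

test_that("least squares agrees with a brute-force normal-equations oracle", {
  sim <- dense_sim(n_species = 4, n_events = 5, k_true = 3, noise_sd = 0.2,
                   seed = 7)
  k <- 2.5
  fit <- fit_fd_given_k(sim$table, k = k)
  X <- build_design(sim$table)$matrix
  y <- log(sim$table$pc_day - k)
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$beta), unname(drop(beta_oracle)), tolerance = 1e-8)
})

test_that("offset domain and design rank are policed", {
  tab <- tiny_table()
  expect_error(fit_fd_given_k(tab, k = min(tab$pc_day)),
               class = "devtiming_domain_error")
  expect_error(fit_fd_given_k(tab, k = -1), class = "devtiming_domain_error")
  # with no primate species the interaction columns are identically zero,
  # which the rank check must flag by name
  no_prim <- dplyr::mutate(tab, is_primate = FALSE)
  expect_error(fit_fd_given_k(no_prim, k = 1), "primate_x",
               class = "devtiming_rank_error")
})

test_that("the fixed-offset historical variant is honoured", {
  tab <- tiny_table()
  fit <- fit_fd(tab, k = 7)
  expect_identical(fit$k, 7)
  expect_false(fit$k_estimated)
  expect_equal(unname(fit$fitted_log),
               unname(drop(fit$design$matrix %*% fit$beta)))
})

test_that("correlation maximization recovers a noiseless offset", {
  sim <- dense_sim(n_species = 4, n_events = 6, k_true = 5, noise_sd = 0,
                   seed = 2)
  est <- estimate_k(sim$table)
  expect_lt(abs(est$k_star - 5), est$grid_step)
  expect_gte(est$correlation, 1 - 1e-9)
  expect_gt(est$k_star, 0)
  expect_lt(est$k_star, min(sim$table$pc_day))
  expect_true(all(est$correlation_profile$correlation >= -1 &
                    est$correlation_profile$correlation <= 1, na.rm = TRUE))
})

test_that("the grid maximizer agrees with a 10x finer brute-force grid", {
  sim <- dense_sim(n_species = 4, n_events = 6, k_true = 4, noise_sd = 0.15,
                   seed = 5)
  coarse <- estimate_k(sim$table, grid_points = 50, refine = FALSE)
  fine <- estimate_k(sim$table, grid_points = 500, refine = FALSE)
  expect_lt(abs(coarse$k_star - fine$k_star), coarse$grid_step)
  # refinement never decreases the achieved correlation
  refined <- estimate_k(sim$table, grid_points = 50, refine = TRUE)
  expect_gte(refined$correlation, coarse$correlation)
})

test_that("predictions recover held-out noiseless cells and exceed the offset", {
  sim <- dense_sim(n_species = 4, n_events = 6, k_true = 5, noise_sd = 0,
                   seed = 3)
  tab <- sim$table
  held <- tab[7, ]
  fit <- fit_fd_given_k(tab[-7, ], k = 5)
  pred <- predict(fit, held[c("species", "event")])
  expect_equal(pred, held$pc_day, tolerance = 1e-6)
  # range: exp(.) + k > k for every encodable query
  all_q <- tidyr::expand_grid(species = unique(tab$species),
                              event = unique(tab$event))
  expect_true(all(predict(fit, all_q) > fit$k))
})

test_that("in-sample and query predictions are invariant to the base choice", {
  sim <- dense_sim(n_species = 5, n_events = 6, k_true = 4, noise_sd = 0.1,
                   seed = 9)
  tab <- sim$table
  f1 <- fit_fd_given_k(tab, k = 2)
  sp <- sort(unique(tab$species)); ev <- sort(unique(tab$event))
  f2 <- fit_fd_given_k(tab, k = 2, base_species = sp[3], base_event = ev[4])
  expect_equal(f1$fitted_log, f2$fitted_log, tolerance = 1e-8)
  q <- tidyr::expand_grid(species = sp, event = ev)
  expect_equal(predict(f1, q), predict(f2, q), tolerance = 1e-8)
})

test_that("coefficient recovery sharpens as noise shrinks", {
  err_at <- function(noise_sd) {
    errs <- vapply(1:20, function(s) {
      spec <- synthetic_spec(n_species = 4, n_events = 5, n_primates = 1,
                             k_true = 5, noise_sd = noise_sd,
                             missing_fraction = 0, seed = 100 + s)
      recovery_experiment(spec, grid_points = 80, loo = FALSE)$max_beta_abs_error
    }, numeric(1))
    mean(errs)
  }
  e <- vapply(c(0.1, 0.01, 0.001), err_at, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("fit metadata, tidy output and JSON round trip are coherent", {
  tab <- tiny_table()
  fit <- fit_fd(tab)
  td <- tidy(fit)
  expect_tibble_cols(td, c("term", "estimate"))
  expect_equal(nrow(td), length(fit$beta))
  gl <- glance(fit)
  expect_equal(gl$n_params, length(fit$beta) + 1)  # + separately estimated k
  expect_true(gl$r_squared_log <= 1)

  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  q <- tidyr::expand_grid(species = unique(tab$species),
                          event = unique(tab$event))
  expect_equal(predict(back, q), predict(fit, q), tolerance = 1e-12)

  comp <- complete_table(fit)
  expect_equal(nrow(comp), 4 * 5)
  expect_true(all(comp$source %in% c("observed", "predicted")))
  expect_s3_class(autoplot(fit), "ggplot")
})
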