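# Fixture builders shared across test files. Everything is generated in code.

# A small hand-written table with both primates and all three event classes.
tiny_table <- function() {
  tibble::tibble(
    species = rep(c("mouse", "rat", "cat", "macaque"), each = 5),
    event = rep(paste0("ev", 1:5), times = 4),
    pc_day = c(
      10, 12, 14, 20, 30,
      11, 13, 16, 23, 35,
      18, 22, 27, 40, 62,
      35, 45, 55, 80, 130
    ),
    is_primate = rep(c(FALSE, FALSE, FALSE, TRUE), each = 5),
    event_class = rep(c("cortical", "limbic", "other", "cortical", "limbic"),
                      times = 4)
  )
}

# Dense noiseless (or noisy) table drawn from the additive-log generative
# model; returns both the table and its generating spec.
dense_sim <- function(n_species = 4, n_events = 5, k_true = 5, noise_sd = 0,
                      seed = 1, missing_fraction = 0, ...) {
  spec <- synthetic_spec(
    n_species = n_species, n_events = n_events,
    n_primates = max(1, round(n_species / 4)),
    k_true = k_true, noise_sd = noise_sd,
    missing_fraction = missing_fraction, seed = seed, ...
  )
  generate_events(spec)
}

expect_tibble_cols <- function(df, cols) {
  testthat::expect_s3_class(df, "tbl_df")
  testthat::expect_true(all(cols %in% names(df)))
}
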