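test_that("window tiling matches floor division and rejects short sessions", {
  cfg <- analysis_config()
  expect_equal(nrow(make_windows(4650L, cfg)), 93)
  expect_equal(nrow(make_windows(2900L, cfg)), 58)
  expect_error(make_windows(49L, cfg), class = "pdcsync_config_error")

  w <- make_windows(200L, cfg)
  expect_equal(w$window_index, 0:3)
  expect_equal(w$start_s, c(0, 50, 100, 150))
  expect_equal(w$end_s - w$start_s, rep(50, 4))

  cfg2 <- analysis_config(window_length_s = 50, window_overlap_s = 25)
  w2 <- make_windows(150L, cfg2)
  expect_equal(w2$start_s, c(0, 25, 50, 75, 100))
})

test_that("test_window returns one result per direction with valid p-values", {
  set.seed(301)
  seg <- matrix(rnorm(3 * 60), 3, 60)
  rownames(seg) <- c("A", "B", "C")
  cfg <- analysis_config(n_surrogates = 19, rng_seed = 5)
  res <- test_window(seg, cfg)
  expect_equal(nrow(res), 6)
  expect_setequal(paste(res$leader, res$pacer), c(
    "A B", "B A", "A C", "C A", "B C", "C B"
  ))
  # add-one rule: p-values live on {1/(n+1), ..., 1} and are never zero
  expect_true(all(res$p_value >= 1 / 20))
  expect_true(all(res$p_value <= 1))
  expect_equal(res$significant, res$p_value < cfg$alpha / cfg$correction_divisor)
})

test_that("strong coupling attains the minimal attainable p-value", {
  set.seed(302)
  coeffs <- list(matrix(c(0.5, 0.8, 0, 0.3), 2, 2)) # 1 drives 2, hard
  seg <- simulate_var_segment(coeffs, 50)
  rownames(seg) <- c("L", "P")
  cfg <- analysis_config(n_surrogates = 99, rng_seed = 1, order = 1)
  res <- test_window(seg, cfg)
  true_dir <- res[res$leader == "L" & res$pacer == "P", ]
  expect_equal(true_dir$p_value, 1 / 100) # beats all 99 surrogates
  expect_true(true_dir$significant)
})

test_that("the synchrony grid is reproducible bit-for-bit from the seed", {
  sc <- standard_scenarios(duration_s = 250, rng_seed = 9)$null_triad
  rec <- simulate_session(sc)$recording
  cfg <- analysis_config(n_surrogates = 19, rng_seed = 33)
  g1 <- compute_sync_grid(rec, cfg)
  g2 <- compute_sync_grid(rec, cfg)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_equal(nrow(g1), 5 * 6) # windows x directed pairs
  # a different master seed gives different surrogate draws
  g3 <- compute_sync_grid(rec, analysis_config(n_surrogates = 19, rng_seed = 34))
  expect_false(identical(g1$p_value, g3$p_value))
})

test_that("null false-positive rate stays near the corrected level (smoke)", {
  sc <- standard_scenarios(duration_s = 600, rng_seed = 21)$null_triad
  rec <- simulate_session(sc)$recording
  # 99 surrogates so the p-value floor (0.01) sits below the 0.0167 threshold
  cfg <- analysis_config(n_surrogates = 99, rng_seed = 21)
  grid <- compute_sync_grid(rec, cfg)
  # 12 windows x 6 directions = 72 trials at nominal 0.0167; a loose bound
  # guards against gross miscalibration without stochastic flakiness
  expect_lt(mean(grid$significant), 0.12)
})

test_that("detection power is non-decreasing in coupling strength", {
  fracs <- vapply(c(0.2, 0.4, 0.6), function(s) {
    sc <- standard_scenarios(strength = s, duration_s = 2500,
                             rng_seed = 50)$unidirectional
    rec <- simulate_session(sc)$recording
    cfg <- analysis_config(n_surrogates = 99, rng_seed = 50)
    grid <- compute_sync_grid(rec, cfg)
    mean(grid$significant[grid$leader == "P1" & grid$pacer == "P2"])
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[3], fracs[1])
})

test_that("grid serialization round-trips through CSV plus metadata", {
  sc <- standard_scenarios(duration_s = 200, rng_seed = 3)$null_triad
  rec <- simulate_session(sc)$recording
  cfg <- analysis_config(n_surrogates = 19, rng_seed = 3)
  grid <- compute_sync_grid(rec, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sync_grid(grid, f)
  back <- read_sync_grid(f)
  attr(grid, "n_surrogate_failures") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(grid))
  expect_equal(attr(back, "total_windows"), attr(grid, "total_windows"))
  expect_equal(attr(back, "config")$rng_seed, cfg$rng_seed)
})

test_that("window-length calibration honors tolerance edge cases", {
  gen <- function(seed) {
    sc <- standard_scenarios(duration_s = 350, rng_seed = seed)$null_triad
    simulate_session(sc)$recording
  }
  cfg <- analysis_config(n_surrogates = 19, rng_seed = 2)
  # vacuous tolerance: smallest candidate wins
  rep1 <- calibrate_window_length(c(60, 100), gen, n_replicates = 1,
                                  tolerance = 1, config = cfg)
  expect_equal(rep1$chosen_length_s, 60)
  # impossible tolerance with nonzero FP: largest + warning
  rep0 <- suppressWarnings(
    calibrate_window_length(c(60, 100), gen, n_replicates = 1,
                            tolerance = -1, config = cfg)
  )
  expect_equal(rep0$chosen_length_s, 100)
  expect_true(rep0$fallback_warning)
  expect_error(calibrate_window_length(numeric(0), gen),
               class = "pdcsync_config_error")
})
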