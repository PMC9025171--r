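test_that("null segments have negligible cross-correlation at short lags", {
  set.seed(501)
  x <- simulate_var_segment(list(diag(0.5, 2)), 10000)
  for (lag in 0:5) {
    r <- cor(x[1, 1:(10000 - lag)], x[2, (1 + lag):10000])
    expect_lt(abs(r), 0.05)
  }
})

test_that("directed coupling shows up as lagged correlation asymmetry", {
  set.seed(502)
  A <- diag(0.5, 2)
  A[2, 1] <- 0.6
  x <- simulate_var_segment(list(A), 10000)
  n <- ncol(x)
  fwd <- cor(x[1, 1:(n - 1)], x[2, 2:n]) # 1 leads 2
  rev <- cor(x[2, 1:(n - 1)], x[1, 2:n])
  expect_gt(fwd - rev, 0.2)
})

test_that("simulation is deterministic per seed, jointly with ground truth", {
  sc <- standard_scenarios(duration_s = 300, rng_seed = 77)$unidirectional
  a <- simulate_session(sc)
  b <- simulate_session(sc)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(ground_truth_windows(a$scenario, 50),
                   ground_truth_windows(b$scenario, 50))
  sc2 <- sc
  sc2$rng_seed <- 78L
  expect_false(identical(simulate_session(sc2)$recording$data,
                         a$recording$data))
})

test_that("ground-truth labels follow segment interval arithmetic", {
  d <- diag(0.5, 3)
  cpl <- d
  cpl[2, 1] <- 0.6
  sc <- simulation_scenario(
    segments = list(
      list(start_s = 0, end_s = 250, coupling = list(d)),
      list(start_s = 250, end_s = 500, coupling = list(cpl)),
      list(start_s = 500, end_s = 760, coupling = list(d))
    ),
    duration_s = 760
  )
  gt <- ground_truth_windows(sc, 50)
  coupled <- gt$window_index[which(gt$coupled)]
  expect_equal(coupled, 5:9) # [250, 500) at 50 s tiles
  expect_equal(gt$edges[[6]], "P1->P2")
  # boundaries at 250 and 500 fall on the tiling: no mixed windows
  expect_equal(nrow(gt), 15)
  expect_false(any(gt$mixed))

  # a boundary off the tiling produces a mixed window
  sc2 <- simulation_scenario(
    segments = list(
      list(start_s = 0, end_s = 230, coupling = list(d)),
      list(start_s = 230, end_s = 500, coupling = list(cpl))
    ),
    duration_s = 500
  )
  gt2 <- ground_truth_windows(sc2, 50)
  expect_true(gt2$mixed[gt2$window_index == 4]) # [200, 250) straddles 230
  expect_false(gt2$mixed[gt2$window_index == 5])
})

test_that("null scenarios are edge-free and the catalogue is complete", {
  gt <- ground_truth_windows(standard_scenarios()$null_triad, 50)
  expect_true(all(!gt$coupled))
  expect_true(all(lengths(gt$edges) == 0))

  cat_ <- standard_scenarios()
  expect_gte(length(cat_), 5)
  expect_named(cat_, c("null_triad", "unidirectional", "mutual",
                       "triad_cascade", "nonstationary_null"))
  A <- cat_$null_triad$segments[[1]]$coupling[[1]]
  expect_true(all(A[row(A) != col(A)] == 0))
  # cascade drives the third channel from both clients
  Ac <- cat_$triad_cascade$segments[[1]]$coupling[[1]]
  expect_true(Ac[3, 1] > 0 && Ac[3, 2] > 0)
})

test_that("positivity transform and trends shape the observed signal", {
  sc <- standard_scenarios(duration_s = 200, rng_seed = 5)$null_triad
  sc$positivity_transform <- "softplus_shift"
  rec <- simulate_session(sc)$recording
  expect_true(all(rec$data > 0))

  scn <- standard_scenarios(duration_s = 2000, rng_seed = 5)$nonstationary_null
  recn <- simulate_session(scn)$recording
  # opposing linear trends: channel 1 drifts up, channel 2 down
  late <- 1800:2000
  early <- 1:200
  expect_gt(mean(recn$data[1, late]) - mean(recn$data[1, early]), 3)
  expect_lt(mean(recn$data[2, late]) - mean(recn$data[2, early]), -3)
})

test_that("unstable or malformed scenarios are rejected", {
  expect_error(simulate_var_segment(list(diag(1.1, 2)), 100),
               class = "pdcsync_scenario_error")
  expect_error(
    simulation_scenario(
      segments = list(list(start_s = 0, end_s = 100, coupling = list(diag(2, 3)))),
      duration_s = 100
    ),
    class = "pdcsync_scenario_error"
  )
  expect_error(
    simulation_scenario(
      segments = list(list(start_s = 0, end_s = 80, coupling = list(diag(0.5, 3)))),
      duration_s = 100
    ),
    class = "pdcsync_config_error"
  )
})

test_that("simulated sessions round-trip through the wide CSV dialect", {
  sc <- standard_scenarios(duration_s = 150, rng_seed = 8)$unidirectional
  sim <- simulate_session(sc)
  f <- withr::local_tempfile(fileext = ".csv")
  write_simulated_session(sim, f, window_length_s = 50)
  series <- read_session_csv(f)
  expect_named(series, c("P1", "P2", "P3"))
  expect_equal(series$P1$values, unname(sim$recording$data["P1", ]))
  truth <- jsonlite::fromJSON(paste0(f, ".truth.json"))
  expect_equal(truth$window_length_s, 50)
  expect_equal(nrow(truth$windows), 3)
})
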