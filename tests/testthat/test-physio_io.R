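test_that("CSV read-back is the identity and write/read round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,time_s,value", "P1,0,1.0", "P1,1,2.0", "P1,2,3.0"), f)
  s <- read_physio_csv(f)[["P1"]]
  expect_s3_class(s, "physio_series")
  expect_equal(s$values, c(1, 2, 3))
  expect_equal(s$start_time_s, 0)

  g <- withr::local_tempfile(fileext = ".csv")
  write_physio_csv(s, g)
  s2 <- read_physio_csv(g)[["P1"]]
  expect_equal(s2$values, s$values)
  expect_equal(s2$start_time_s, s$start_time_s)
})

test_that("gaps and bad values in series input are rejected with named rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,time_s,value", "P1,0,1.0", "P1,1,2.0", "P1,3,3.0"), f)
  expect_error(read_physio_csv(f), class = "pdcsync_sampling_error")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,time_s,value", "P1,0,1.0", "P1,1,oops"), g)
  expect_error(read_physio_csv(g), class = "pdcsync_validation_error")

  expect_error(read_physio_csv(f, value_column = "nope"),
               class = "pdcsync_input_error")
})

test_that("intersect alignment trims to the common span", {
  # samples at t = 0..100 and t = 10..120; common clock samples are 10..100
  a <- physio_series(seq_len(101), "A", start_time_s = 0)
  b <- physio_series(seq_len(111), "B", start_time_s = 10)
  rec <- align_session(list(a, b))
  expect_equal(ncol(rec$data), 91)
  expect_equal(rec$start_time_s, 10)
  # row content: a's samples 11..101, b's samples 1..91
  expect_equal(unname(rec$data["A", ]), 11:101)
  expect_equal(unname(rec$data["B", ]), 1:91)
})

test_that("alignment order does not change matrix content, only row order", {
  a <- physio_series(rnorm(120), "A", start_time_s = 5)
  b <- physio_series(rnorm(100), "B", start_time_s = 0)
  r1 <- align_session(list(a, b))
  r2 <- align_session(list(b, a))
  expect_equal(r1$data["A", ], r2$data["A", ])
  expect_equal(r1$data["B", ], r2$data["B", ])
})

test_that("strict policy and degenerate overlaps error appropriately", {
  a <- physio_series(rnorm(50), "A")
  b <- physio_series(rnorm(50), "B")
  rec <- align_session(list(a, b), policy = "strict")
  expect_equal(ncol(rec$data), 50)

  c2 <- physio_series(rnorm(60), "B")
  expect_error(align_session(list(a, c2), policy = "strict"),
               class = "pdcsync_alignment_error")
  d <- physio_series(rnorm(40), "D", start_time_s = 500)
  expect_error(align_session(list(a, d)), class = "pdcsync_alignment_error")
  e <- physio_series(rnorm(50), "E", sampling_rate_hz = 2)
  expect_error(align_session(list(a, e)), class = "pdcsync_sampling_error")
})

test_that("episode tracks validate, sort, and round-trip through CSV and JSON", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("episode_id,start_s,end_s", "TE2,160,800", "TE1,0,160"), f)
  tr <- read_episode_track(f)
  expect_equal(tr$episode_id, c("TE1", "TE2"))
  expect_equal(tr$end_s - tr$start_s, c(160, 640))

  j <- withr::local_tempfile(fileext = ".json")
  write_episode_track(tr, j)
  tr2 <- read_episode_track(j)
  expect_equal(tr2$start_s, tr$start_s)
  expect_equal(tr2$episode_id, tr$episode_id)

  expect_error(episode_track(data.frame(episode_id = "X", start_s = 100, end_s = 50)),
               class = "pdcsync_validation_error")
  expect_error(
    episode_track(data.frame(episode_id = c("A", "B"),
                             start_s = c(0, 50), end_s = c(100, 150))),
    class = "pdcsync_validation_error"
  )
})
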