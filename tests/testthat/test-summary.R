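tabs <- case_count_tables()
fx <- session_fixture_grids()

test_that("fixture grids reproduce the printed case count tables exactly", {
  t3 <- directed_counts(fx$session3)
  expect_equal(t3$counts, tabs$session3$counts)
  expect_equal(t3$unique_sync_windows, 29L)
  expect_equal(t3$total_windows, 93L)

  t14 <- directed_counts(fx$session14)
  expect_equal(t14$counts, tabs$session14$counts)
  expect_equal(t14$unique_sync_windows, 10L)
  expect_equal(t14$total_windows, 58L)
})

test_that("unique windows count each window once across directions", {
  g <- tiny_grid(data.frame(window_index = c(2L, 2L),
                            leader = c("A", "B"), pacer = c("B", "A")), 10L)
  tab <- directed_counts(g)
  expect_equal(sum(tab$counts), 2L)
  expect_equal(tab$unique_sync_windows, 1L)
  # no significance at all
  g0 <- tiny_grid(data.frame(window_index = integer(), leader = character(),
                             pacer = character()), 5L)
  t0 <- directed_counts(g0)
  expect_true(all(t0$counts == 0))
  expect_equal(t0$unique_sync_windows, 0L)
  # invariant: unique <= sum of counts, equality iff no multiplicity
  expect_lte(directed_counts(fx$session3)$unique_sync_windows,
             sum(directed_counts(fx$session3)$counts))
})

test_that("session time percentages match the printed figures", {
  expect_equal(round_trip <- session_time_percent(tabs$session3),
               100 * 29 / 93)
  expect_equal(percent_label(session_time_percent(tabs$session3)), "31.2%")
  expect_equal(percent_label(session_time_percent(tabs$session14)), "17.2%")
  tc <- session_time_percent(tabs$session3, "pairs",
                             pairs = c("Therapist", "Costas"))
  expect_equal(percent_label(tc), "18.3%")
  # invariance under participant relabeling
  perm <- c("Therapist", "Demetra", "Costas")
  tp <- sync_table(tabs$session3$counts[perm, perm], 93, 29)
  expect_equal(session_time_percent(tp), session_time_percent(tabs$session3))
})

test_that("half-up rounding governs the presentation labels", {
  expect_equal(percent_label(31.15), "31.2%")
  expect_equal(percent_label(17.24), "17.2%")
  expect_equal(percent_label(39.0625, digits = 0), "39%")
})

test_that("increased-synchrony windows carry multiplicity and all-three flags", {
  inc3 <- increased_ips_windows(fx$session3)
  expect_equal(nrow(inc3), 4) # printed: four windows with increased IPS
  expect_equal(sum(inc3$all_three), 1)
  all3 <- inc3[inc3$all_three, ]
  expect_equal(all3$n_edges, 4)

  inc14 <- increased_ips_windows(fx$session14)
  expect_equal(nrow(inc14), 3)

  g <- tiny_grid(data.frame(window_index = c(1L, 1L, 4L),
                            leader = c("C", "C", "A"),
                            pacer = c("A", "B", "B")), 10L)
  inc <- increased_ips_windows(g)
  expect_equal(inc$window_index, 1L)
  expect_equal(inc$n_edges, 2L)
  expect_false(inc$all_three) # the A-B dyad is not linked in window 1
  # a window linking every dyad is flagged
  g2 <- tiny_grid(data.frame(window_index = c(1L, 1L, 1L),
                             leader = c("A", "B", "C"),
                             pacer = c("B", "C", "A")), 10L)
  expect_true(increased_ips_windows(g2)$all_three)
})

test_that("clustering groups sync windows within the allowed gap", {
  g <- tiny_grid(data.frame(window_index = c(3L, 4L, 6L),
                            leader = "A", pacer = "B"), 12L)
  cl <- cluster_windows(g, max_gap = 1)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start_window, 3L)
  expect_equal(cl$end_window, 6L)

  g2 <- tiny_grid(data.frame(window_index = c(3L, 9L),
                             leader = "A", pacer = "B"), 12L)
  expect_equal(nrow(cluster_windows(g2, max_gap = 1)), 2)
  expect_equal(nrow(cluster_windows(g2, max_gap = 5)), 1)

  g3 <- tiny_grid(data.frame(window_index = integer(), leader = character(),
                             pacer = character()), 5L)
  expect_equal(nrow(cluster_windows(g3)), 0)
})

test_that("episode percentages recompute the printed episode figures", {
  es <- suppressMessages(episode_summary(fx$session3))
  te4 <- es[es$episode_id == "TE4", ]
  te7 <- es[es$episode_id == "TE7", ]
  expect_equal(te4$n_sync_windows, 5)
  expect_equal(te4$pct_episode_time, 100 * 5 * 50 / 640)
  expect_equal(percent_label(te4$pct_episode_time, 0), "39%")
  expect_equal(te7$n_sync_windows, 5)
  expect_equal(percent_label(te7$pct_episode_time, 0), "28%")
  # annotations pass through
  expect_equal(te4$softa_composite, 6)
})

test_that("episode assignment uses window midpoints and caps at 100", {
  ep <- episode_track(data.frame(episode_id = c("E1", "E2"),
                                 start_s = c(0, 120), end_s = c(120, 500)))
  # windows 0..9 of 50 s; window 2 = [100,150) has midpoint 125 -> E2
  g <- tiny_grid(data.frame(window_index = c(0L, 2L),
                            leader = "A", pacer = "B"), 10L, episodes = ep)
  es <- episode_summary(g)
  expect_equal(es$n_sync_windows, c(1, 1))
  expect_equal(es$pct_episode_time[1], 100 * 1 * 50 / 120)
  # short episode with one sync window would exceed 100 without the cap
  ep2 <- episode_track(data.frame(episode_id = "S", start_s = 100, end_s = 130))
  es2 <- suppressMessages(episode_summary(g, ep2))
  expect_equal(es2$pct_episode_time, 100)
})

test_that("leading network reconciles with the count table and balances", {
  net3 <- leading_network(tabs$session3)
  led <- setNames(net3$participants$windows_leading,
                  net3$participants$participant_id)
  expect_equal(led[["Costas"]], 17)
  expect_equal(led[["Demetra"]], 5)
  expect_equal(led[["Therapist"]], 14)
  expect_equal(sum(net3$participants$windows_leading), sum(tabs$session3$counts))
  expect_equal(sum(net3$participants$windows_pacing), sum(tabs$session3$counts))

  net14 <- leading_network(tabs$session14)
  led14 <- setNames(net14$participants$windows_leading,
                    net14$participants$participant_id)
  expect_equal(unname(led14[c("Demetra", "Costas", "Therapist")]), c(5, 3, 5))
  # the later session is the more balanced network
  expect_gt(net14$balance, net3$balance)

  uniform <- sync_table(matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3])),
                        100, 12)
  expect_equal(leading_network(uniform)$balance, 1)
  zero <- sync_table(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])),
                     10, 0)
  expect_equal(suppressMessages(leading_network(zero))$balance, 1)
})

test_that("between-session comparison reports the printed contrasts", {
  rep <- compare_sessions(tabs$session3, tabs$session14)
  expect_equal(rep$delta_pct_session_time, 100 * 10 / 58 - 100 * 29 / 93)
  # at the printed precision: 31.2 - 17.2 = 14.0 percentage points
  printed_delta <- round_half_up(100 * 29 / 93, 1) - round_half_up(100 * 10 / 58, 1)
  expect_equal(printed_delta, 14.0)
  # therapist-involving directed sums: 27 in session 3, 8 in session 14
  tsum <- function(tab) {
    sum(tab$counts["Therapist", ]) + sum(tab$counts[, "Therapist"])
  }
  expect_equal(tsum(tabs$session3), 27)
  expect_equal(tsum(tabs$session14), 8)
  expect_lt(rep$proportion_test$p_value, 0.07) # descriptive convention
  expect_gt(rep$balance_delta, 0)

  same <- compare_sessions(tabs$session3, tabs$session3)
  expect_true(all(same$per_pair$delta_windows == 0))
  expect_equal(same$proportion_test$p_value, 1)

  other <- sync_table(matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y"))),
                      10, 0)
  expect_error(compare_sessions(tabs$session3, other),
               class = "pdcsync_comparison_error")
})
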