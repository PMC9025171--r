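#' Printed count tables of the published couple-therapy case
#'
#' The published single-case study reports, for two therapy sessions of a
#' couple (Demetra, Costas) and their therapist, the directed count tables of
#' significant 50 s synchrony windows: session 3 (93 windows, 29 in
#' synchrony) and the penultimate session (58 windows, 10 in synchrony).
#' These printed tables are the reference inputs for the summary arithmetic;
#' the underlying physiological signals are not public.
#'
#' @return Named list of two [sync_table()]s: `session3`, `session14`.
#' @examples
#' tabs <- case_count_tables()
#' session_time_percent(tabs$session3) # 31.18...
#' @export
case_count_tables <- function() {
  ids <- c("Demetra", "Costas", "Therapist")
  # rows = pacing role, columns = leading role
  c3 <- matrix(c(
    0, 8, 6,
    1, 0, 8,
    4, 9, 0
  ), 3, 3, byrow = TRUE, dimnames = list(ids, ids))
  c14 <- matrix(c(
    0, 1, 4,
    4, 0, 1,
    1, 2, 0
  ), 3, 3, byrow = TRUE, dimnames = list(ids, ids))
  list(
    session3 = sync_table(c3, total_windows = 93, unique_sync_windows = 29),
    session14 = sync_table(c14, total_windows = 58, unique_sync_windows = 10)
  )
}

# Window-level edge layouts. The published tables give only marginal counts;
# these synthetic layouts are one placement consistent with every printed
# marginal: directed counts, unique window totals, the number of
# increased-synchrony windows (4 in session 3 incl. one all-three window;
# 3 in session 14), and 5 sync windows inside each of the two episodes whose
# durations are printed (TE4 640 s, TE7 880 s).
fixture_edges_session3 <- function() {
  e <- function(w, leader, pacer) tibble(window_index = w, leader = leader, pacer = pacer)
  dplyr::bind_rows(
    # early cluster
    e(3, "Costas", "Therapist"), e(4, "Therapist", "Costas"),
    e(5, "Costas", "Therapist"), e(8, "Therapist", "Demetra"),
    # TE4 cluster (windows 14-18, midpoints inside [600, 1240))
    e(14, "Costas", "Demetra"),
    e(15, "Costas", "Demetra"), e(15, "Demetra", "Therapist"),
    e(15, "Therapist", "Demetra"),
    e(16, "Therapist", "Costas"),
    e(17, "Costas", "Therapist"), e(17, "Therapist", "Costas"),
    e(18, "Costas", "Therapist"),
    # mid-session clusters
    e(26, "Costas", "Demetra"), e(27, "Costas", "Therapist"),
    e(28, "Therapist", "Costas"), e(31, "Demetra", "Therapist"),
    e(34, "Therapist", "Demetra"), e(35, "Therapist", "Costas"),
    # TE7 (windows with midpoints inside [2000, 2880))
    e(45, "Costas", "Therapist"),
    e(53, "Therapist", "Costas"),
    # the all-three window: mutual couple synchrony, both leading therapist
    e(54, "Demetra", "Costas"), e(54, "Costas", "Demetra"),
    e(54, "Demetra", "Therapist"), e(54, "Costas", "Therapist"),
    e(55, "Costas", "Demetra"),
    e(56, "Costas", "Demetra"), e(56, "Therapist", "Demetra"),
    # late clusters
    e(60, "Costas", "Demetra"), e(61, "Therapist", "Costas"),
    e(62, "Costas", "Therapist"), e(66, "Demetra", "Therapist"),
    e(70, "Therapist", "Demetra"), e(71, "Costas", "Demetra"),
    e(75, "Therapist", "Demetra"),
    e(80, "Costas", "Therapist"), e(81, "Therapist", "Costas")
  )
}

fixture_edges_session14 <- function() {
  e <- function(w, leader, pacer) tibble(window_index = w, leader = leader, pacer = pacer)
  dplyr::bind_rows(
    e(5, "Costas", "Demetra"),
    e(10, "Demetra", "Costas"), e(10, "Therapist", "Demetra"),
    e(11, "Demetra", "Costas"), e(11, "Costas", "Therapist"),
    e(20, "Demetra", "Costas"), e(21, "Demetra", "Costas"),
    e(30, "Therapist", "Demetra"), e(30, "Demetra", "Therapist"),
    e(31, "Therapist", "Demetra"), e(45, "Therapist", "Demetra"),
    e(46, "Therapist", "Costas"), e(50, "Costas", "Therapist")
  )
}

build_fixture_grid <- function(edges, total_windows, session_id,
                               episodes = NULL) {
  ids <- c("Demetra", "Costas", "Therapist")
  cfg <- analysis_config(window_length_s = 50, n_surrogates = 999)
  pairs <- expand.grid(leader = ids, pacer = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$leader != pairs$pacer, ]
  full <- tidyr::crossing(window_index = 0:(total_windows - 1L),
                          as_tibble(pairs))
  edges$significant <- TRUE
  res <- left_join(full, edges, by = c("window_index", "leader", "pacer")) |>
    mutate(
      significant = !is.na(.data$significant),
      start_s = .data$window_index * 50,
      end_s = .data$start_s + 50,
      stat = ifelse(.data$significant, 0.6, 0.1),
      p_value = ifelse(.data$significant, 0.001, 0.5),
      n_surrogates = 999L,
      order_p = 1L
    ) |>
    select("window_index", "start_s", "end_s", "leader", "pacer",
           "stat", "p_value", "significant", "n_surrogates", "order_p")
  sync_grid(res, session_id = session_id, participant_ids = ids,
            config = cfg, total_windows = total_windows, episodes = episodes)
}

#' Synthetic window-level grids consistent with the published case tables
#'
#' The published study prints count tables, not window positions. These
#' synthetic grids place significant edges on concrete windows so that every
#' printed marginal is reproduced exactly (see [case_count_tables()]),
#' including the number of increased-synchrony windows and — for session 3 —
#' five sync windows inside each of the two topical episodes whose durations
#' are printed (TE4: 640 s, TE7: 880 s). Use them to exercise the summary
#' stage end to end; they are reconstructions, not the study's data.
#'
#' @return List: `session3` and `session14` [sync_grid()]s (session 3 carries
#'   its two-episode [episode_track()]), plus `episodes_session3`.
#' @export
session_fixture_grids <- function() {
  episodes <- episode_track(tibble(
    episode_id = c("TE4", "TE7"),
    start_s = c(600, 2000),
    end_s = c(1240, 2880),
    label = c("motherhood conflicts introduced", "motherhood theme elaborated"),
    softa_composite = c(6, 4)
  ))
  list(
    session3 = build_fixture_grid(fixture_edges_session3(), 93L,
                                  "case-session3-synthetic", episodes),
    session14 = build_fixture_grid(fixture_edges_session14(), 58L,
                                   "case-session14-synthetic"),
    episodes_session3 = episodes
  )
}
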