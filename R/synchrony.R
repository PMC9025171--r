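#' Tile a session into analysis windows
#'
#' Windows are half-open `[k*step, k*step + L)` tiles starting at t = 0 of the
#' aligned recording, with `step = L - overlap` (default: contiguous,
#' non-overlapping). A trailing partial window is discarded, so with no
#' overlap the count is `floor(T / L)`.
#'
#' @param recording A [session_recording()], or a single integer sample count.
#' @param config An [analysis_config()].
#' @return Tibble with `window_index` (0-based), `start_s`, `end_s`.
#' @export
make_windows <- function(recording, config = analysis_config()) {
  n <- if (inherits(recording, "session_recording")) {
    ncol(recording$data)
  } else {
    as.integer(recording)
  }
  rate <- if (inherits(recording, "session_recording")) {
    recording$sampling_rate_hz
  } else {
    1
  }
  L <- as.integer(round(config$window_length_s * rate))
  step <- L - as.integer(round(config$window_overlap_s * rate))
  if (n < L) {
    abort_config(sprintf(
      "session of %d samples is shorter than one %d-sample window", n, L
    ))
  }
  starts <- seq(0L, n - L, by = step)
  tibble(
    window_index = seq_along(starts) - 1L,
    start_s = starts / rate,
    end_s = (starts + L) / rate
  )
}

# Derived-statistic helper: fit + spectrum + both direction statistics for a
# 2-channel segment at a fixed order.
pair_statistics <- function(sub, p, config) {
  model <- fit_mvar(sub, p, standardize = config$standardize)
  spec <- pdc_spectrum(model, n_freqs = config$n_freqs)
  ids <- rownames(sub)
  c(
    pdc_statistic(spec, directed_pair(ids[1], ids[2]), config$band, config$reducer),
    pdc_statistic(spec, directed_pair(ids[2], ids[1]), config$band, config$reducer)
  )
}

#' Surrogate significance test for one window
#'
#' For each unordered pair of channels in the window, fits a bivariate MVAR
#' (order selected on the observed segment and reused for its surrogates),
#' computes the directed PDC statistic in both directions, and compares each
#' against `n_surrogates` statistics from surrogate segments. P-values use
#' the add-one rule `p = (1 + #\{surrogate >= observed\}) / (n_surrogates + 1)`,
#' so they are never zero; a result is significant when
#' `p < alpha / correction_divisor`.
#'
#' A surrogate whose fit fails is resampled once and, if it fails again,
#' scored as statistic 0 (keeping the denominator fixed); the count of such
#' failures is returned as attribute `n_surrogate_failures`.
#'
#' @param segment M x n numeric matrix with row names = participant ids.
#' @param config An [analysis_config()].
#' @param window_index Window index used (with the master seed) to derive the
#'   per-pair RNG stream.
#' @return Tibble with one row per directed pair: `leader`, `pacer`, `stat`,
#'   `p_value`, `significant`, `n_surrogates`, `order_p`.
#' @export
test_window <- function(segment, config = analysis_config(), window_index = 0L) {
  segment <- as.matrix(segment)
  M <- nrow(segment)
  if (M < 2L) abort_input("test_window needs at least two channels")
  ids <- rownames(segment) %||% paste0("ch", seq_len(M))
  rownames(segment) <- ids
  pairs <- utils::combn(M, 2L)
  thr <- config$alpha / config$correction_divisor
  n_fail <- 0L
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    sub <- segment[c(i, j), , drop = FALSE]
    p <- if (is.numeric(config$order)) {
      as.integer(config$order)
    } else {
      select_order(sub, criterion = config$order,
                   max_order = config$max_order,
                   standardize = config$standardize)
    }
    obs <- pair_statistics(sub, p, config)
    set.seed(derive_seed(config$rng_seed, window_index, k))
    surr <- matrix(0, config$n_surrogates, 2L)
    for (s in seq_len(config$n_surrogates)) {
      stat_s <- NULL
      for (attempt in 1:2) {
        sg <- make_surrogate(sub, config$surrogate_method, min_shift = p)
        stat_s <- tryCatch(pair_statistics(sg, p, config), error = function(e) NULL)
        if (!is.null(stat_s)) break
      }
      if (is.null(stat_s)) {
        n_fail <- n_fail + 1L
        stat_s <- c(0, 0)
      }
      surr[s, ] <- stat_s
    }
    pv <- (1 + colSums(surr >= rep(obs, each = nrow(surr)))) /
      (config$n_surrogates + 1)
    rows[[k]] <- tibble(
      leader = c(ids[i], ids[j]),
      pacer = c(ids[j], ids[i]),
      stat = obs,
      p_value = pv,
      significant = pv < thr,
      n_surrogates = config$n_surrogates,
      order_p = p
    )
  }
  out <- dplyr::bind_rows(rows)
  if (n_fail > 0L) {
    inform(sprintf("%d surrogate fit(s) failed twice and were scored 0", n_fail))
  }
  attr(out, "n_surrogate_failures") <- n_fail
  out
}

#' Construct a synchrony grid from per-window results
#'
#' Mostly used internally by [compute_sync_grid()]; exposed so that grids can
#' be rebuilt from serialized results or from fixture edge lists.
#'
#' @param results Tibble with columns `window_index`, `start_s`, `end_s`,
#'   `leader`, `pacer`, `stat`, `p_value`, `significant`.
#' @param session_id Session identifier.
#' @param participant_ids Participant ids (supplies the table ordering).
#' @param config The [analysis_config()] that produced the results.
#' @param total_windows Number of windows in the session.
#' @param episodes Optional [episode_track()].
#' @return A `sync_grid` tibble with metadata attributes.
#' @export
sync_grid <- function(results, session_id, participant_ids, config,
                      total_windows, episodes = NULL) {
  results <- as_tibble(results)
  need <- c("window_index", "start_s", "end_s", "leader", "pacer",
            "stat", "p_value", "significant")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort_input(sprintf("results lack column(s): %s", paste(miss, collapse = ", ")))
  }
  structure(
    results,
    class = c("sync_grid", class(tibble())),
    session_id = session_id,
    participant_ids = as.character(participant_ids),
    config = config,
    total_windows = as.integer(total_windows),
    episodes = episodes
  )
}

grid_meta <- function(grid, what) attr(grid, what, exact = TRUE)

#' Windowed surrogate-tested synchrony over a whole session
#'
#' Runs [test_window()] on every window of the recording for all
#' `M*(M-1)` directed pairs (6 for a triad). Non-significant results are
#' retained with their p-values but are excluded from every downstream
#' summary; only the significant flag feeds the count tables.
#'
#' Reruns with the same `rng_seed` reproduce the grid bit-for-bit: each
#' (window, pair) surrogate stream is derived from the master seed by stable
#' hashing, independent of execution order.
#'
#' @param recording A [session_recording()].
#' @param config An [analysis_config()].
#' @return A `sync_grid`.
#' @export
compute_sync_grid <- function(recording, config = analysis_config()) {
  stopifnot(inherits(recording, "session_recording"))
  windows <- make_windows(recording, config)
  rate <- recording$sampling_rate_hz
  res <- vector("list", nrow(windows))
  n_fail <- 0L
  for (w in seq_len(nrow(windows))) {
    i0 <- as.integer(round(windows$start_s[w] * rate)) + 1L
    i1 <- as.integer(round(windows$end_s[w] * rate))
    seg <- recording$data[, i0:i1, drop = FALSE]
    tw <- test_window(seg, config, window_index = windows$window_index[w])
    n_fail <- n_fail + attr(tw, "n_surrogate_failures")
    tw$window_index <- windows$window_index[w]
    tw$start_s <- windows$start_s[w]
    tw$end_s <- windows$end_s[w]
    res[[w]] <- tw
  }
  results <- dplyr::bind_rows(res) |>
    select("window_index", "start_s", "end_s", "leader", "pacer",
           "stat", "p_value", "significant", "n_surrogates", "order_p")
  out <- sync_grid(results,
    session_id = recording$session_id,
    participant_ids = recording$participant_ids,
    config = config,
    total_windows = nrow(windows),
    episodes = recording$episodes
  )
  attr(out, "n_surrogate_failures") <- n_fail
  out
}

#' @export
print.sync_grid <- function(x, ...) {
  cat(sprintf(
    "<sync_grid> session '%s': %d windows x %d directed pairs, %d significant\n",
    grid_meta(x, "session_id"), grid_meta(x, "total_windows"),
    length(grid_meta(x, "participant_ids")) * (length(grid_meta(x, "participant_ids")) - 1L),
    sum(x$significant)
  ))
  NextMethod()
}

#' @export
tidy.sync_grid <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.sync_grid <- function(x, ...) {
  cfg <- grid_meta(x, "config")
  tw <- grid_meta(x, "total_windows")
  sig_w <- length(unique(x$window_index[x$significant]))
  tibble(
    session_id = grid_meta(x, "session_id"),
    total_windows = tw,
    n_directed_results = nrow(x),
    n_significant = sum(x$significant),
    unique_sync_windows = sig_w,
    pct_session_time = 100 * sig_w / tw,
    window_length_s = cfg$window_length_s,
    n_surrogates = cfg$n_surrogates,
    threshold = cfg$alpha / cfg$correction_divisor
  )
}

#' Serialize / read a synchrony grid
#'
#' The grid's per-window results go to CSV; session metadata and the
#' configuration snapshot go to a JSON sidecar, so `read_sync_grid()`
#' round-trips the object.
#'
#' @param grid A `sync_grid`.
#' @param csv_path Output CSV path; the sidecar is `<csv_path>.meta.json`.
#' @return `csv_path`, invisibly.
#' @export
write_sync_grid <- function(grid, csv_path) {
  readr::write_csv(as_tibble(grid), csv_path, progress = FALSE)
  cfg <- grid_meta(grid, "config")
  meta <- list(
    session_id = grid_meta(grid, "session_id"),
    participant_ids = as.list(grid_meta(grid, "participant_ids")),
    total_windows = grid_meta(grid, "total_windows"),
    config = unclass(cfg)
  )
  ep <- grid_meta(grid, "episodes")
  if (!is.null(ep)) meta$episodes <- as.data.frame(ep)
  jsonlite::write_json(meta, paste0(csv_path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(csv_path)
}

#' @rdname write_sync_grid
#' @param csv_path Path written by `write_sync_grid()`.
#' @export
read_sync_grid <- function(csv_path) {
  if (!file.exists(csv_path)) abort_input(sprintf("file not found: %s", csv_path))
  meta_path <- paste0(csv_path, ".meta.json")
  if (!file.exists(meta_path)) {
    abort_input(sprintf("missing grid metadata sidecar: %s", meta_path))
  }
  results <- readr::read_csv(csv_path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::fromJSON(meta_path)
  cfg <- do.call(analysis_config, meta$config)
  ep <- if (!is.null(meta$episodes)) episode_track(meta$episodes) else NULL
  sync_grid(results,
    session_id = meta$session_id,
    participant_ids = unlist(meta$participant_ids),
    config = cfg,
    total_windows = meta$total_windows,
    episodes = ep
  )
}

#' Calibrate the window length on coupling-free data
#'
#' Replays the full pipeline over independent null sessions for each
#' candidate window length and picks the smallest candidate whose mean
#' false-positive fraction (significant results over window-direction tests)
#' stays at or below `tolerance` — the shortest window, hence finest temporal
#' resolution, that does not inflate false positives. If no candidate
#' qualifies, the largest is returned with a warning.
#'
#' @param candidates Candidate window lengths in seconds, sorted ascending.
#' @param scenario A coupling-free scenario: a [simulation_scenario()], a
#'   name from [standard_scenarios()], or a function `function(seed)`
#'   returning a [session_recording()].
#' @param n_replicates Independent null sessions per candidate.
#' @param tolerance Acceptable mean false-positive fraction.
#' @param config Base [analysis_config()]; `window_length_s` is overridden
#'   per candidate and replicate seeds are derived from its `rng_seed`.
#' @return A `calibration_report` with the per-length table and
#'   `chosen_length_s`.
#' @export
calibrate_window_length <- function(candidates, scenario = "null_triad",
                                    n_replicates = 5L,
                                    tolerance = NULL,
                                    config = analysis_config()) {
  if (!length(candidates)) abort_config("candidates must be non-empty")
  candidates <- sort(as.numeric(candidates))
  if (is.null(tolerance)) {
    tolerance <- config$alpha / config$correction_divisor * 1.5
  }
  gen <- resolve_null_generator(scenario)
  per <- purrr::map(seq_along(candidates), function(ci) {
    L <- candidates[ci]
    fracs <- vapply(seq_len(n_replicates), function(r) {
      rep_seed <- derive_seed(config$rng_seed, ci, r)
      rec <- gen(rep_seed)
      cfg <- config
      cfg$window_length_s <- L
      cfg$rng_seed <- rep_seed
      grid <- compute_sync_grid(rec, cfg)
      mean(grid$significant)
    }, numeric(1))
    tibble(
      window_length_s = L,
      mean_fp_fraction = mean(fracs),
      sd_fp_fraction = stats::sd(fracs),
      n_replicates = n_replicates
    )
  }) |> dplyr::bind_rows()
  ok <- which(per$mean_fp_fraction <= tolerance)
  warned <- FALSE
  if (length(ok)) {
    chosen <- per$window_length_s[ok[1L]]
  } else {
    chosen <- max(candidates)
    warned <- TRUE
    warn(sprintf(
      "no candidate length met tolerance %.4g; falling back to largest (%g s)",
      tolerance, chosen
    ))
  }
  structure(
    list(
      candidate_lengths_s = candidates,
      per_length = per,
      chosen_length_s = chosen,
      tolerance = tolerance,
      fallback_warning = warned
    ),
    class = "calibration_report"
  )
}

resolve_null_generator <- function(scenario) {
  if (is.function(scenario)) return(scenario)
  if (is.character(scenario)) {
    scenario <- standard_scenarios()[[scenario]] %||%
      abort_config(sprintf("unknown scenario '%s'", scenario))
  }
  if (!inherits(scenario, "simulation_scenario")) {
    abort_config("scenario must be a simulation_scenario, a name, or a function")
  }
  function(seed) {
    sc <- scenario
    sc$rng_seed <- seed
    simulate_session(sc)$recording
  }
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("<calibration_report>\n")
  print(x$per_length)
  cat(sprintf("chosen length: %g s (tolerance %.4g%s)\n", x$chosen_length_s,
              x$tolerance, if (x$fallback_warning) ", fallback" else ""))
  invisible(x)
}

#' @export
tidy.calibration_report <- function(x, ...) x$per_length

#' @export
glance.calibration_report <- function(x, ...) {
  tibble(
    chosen_length_s = x$chosen_length_s,
    tolerance = x$tolerance,
    n_candidates = length(x$candidate_lengths_s),
    fallback = x$fallback_warning
  )
}
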