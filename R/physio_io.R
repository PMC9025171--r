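#' Construct a physiological arousal series
#'
#' A `physio_series` holds one participant's 1 Hz autonomic-arousal signal
#' (for example an absolute-stress-vector style sympathetic index) together
#' with its identity and time origin. All downstream analysis consumes these
#' objects, usually after [align_session()] combines several into a
#' [session_recording()].
#'
#' @param values Numeric vector of arousal values (arbitrary units). Must be
#'   finite and of length >= 1.
#' @param participant_id Short identifier string.
#' @param label Signal name, e.g. `"ASV"`.
#' @param start_time_s Offset of the first sample from session start, seconds.
#' @param sampling_rate_hz Sampling rate; the method targets 1 Hz signals.
#' @return A `physio_series` object.
#' @examples
#' s <- physio_series(c(1, 2, 3), "P1")
#' end_time_s(s)
#' @export
physio_series <- function(values, participant_id, label = "ASV",
                          start_time_s = 0, sampling_rate_hz = 1) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    abort_validation("a physio_series needs at least one sample")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    abort_validation(sprintf(
      "non-finite arousal value at sample %d for participant '%s'",
      bad, participant_id
    ))
  }
  if (!is_scalar_number(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort_validation("sampling_rate_hz must be a positive number")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      label = as.character(label),
      start_time_s = as.numeric(start_time_s),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      values = values
    ),
    class = "physio_series"
  )
}

#' @export
print.physio_series <- function(x, ...) {
  cat(sprintf(
    "<physio_series> %s [%s] %d samples @ %g Hz, t0 = %g s\n",
    x$participant_id, x$label, length(x$values), x$sampling_rate_hz,
    x$start_time_s
  ))
  invisible(x)
}

#' @export
length.physio_series <- function(x) length(x$values)

#' End time (exclusive) of a series in seconds
#'
#' Time convention throughout the package: seconds from session start,
#' half-open intervals `[start, end)`.
#' @param x A `physio_series`.
#' @return End time in seconds.
#' @export
end_time_s <- function(x) {
  stopifnot(inherits(x, "physio_series"))
  x$start_time_s + length(x$values) / x$sampling_rate_hz
}

#' @export
as_tibble.physio_series <- function(x, ...) {
  tibble(
    participant_id = x$participant_id,
    time_s = x$start_time_s + (seq_along(x$values) - 1) / x$sampling_rate_hz,
    value = x$values
  )
}

#' Read physiological series from CSV
#'
#' Accepts the long dialect (one row per sample: id, time, value). If a time
#' column is given, sample spacing is checked against the sampling rate; gaps
#' are an error, not imputed — the windowed model requires contiguous data.
#'
#' @param path CSV file path.
#' @param id_column,value_column,time_column Column names; `time_column = NULL`
#'   skips the spacing check and assumes samples are in order from time 0.
#' @param sampling_rate_hz Expected sampling rate (default 1 Hz).
#' @param tolerance Allowed deviation, in seconds, of each time step from the
#'   nominal sampling interval.
#' @return A named list of `physio_series`, one per distinct id (a list of
#'   length one when the file holds a single participant).
#' @export
read_physio_csv <- function(path, id_column = "participant_id",
                            value_column = "value", time_column = "time_s",
                            sampling_rate_hz = 1, tolerance = 1e-6) {
  if (!file.exists(path)) {
    abort_input(sprintf("file not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(id_column, value_column, time_column)) {
    if (!is.null(col) && !col %in% names(df)) {
      abort_input(sprintf("column '%s' not found in %s", col, path))
    }
  }
  vals_raw <- df[[value_column]]
  if (!is.numeric(vals_raw)) {
    suppressWarnings(vals_num <- as.numeric(vals_raw))
  } else {
    vals_num <- vals_raw
  }
  if (anyNA(vals_num) || !all(is.finite(vals_num))) {
    bad <- which(!is.finite(vals_num))[1L]
    abort_validation(sprintf(
      "non-numeric or missing value in column '%s' at row %d of %s",
      value_column, bad, path
    ))
  }
  df[[value_column]] <- vals_num
  ids <- unique(as.character(df[[id_column]]))
  out <- lapply(ids, function(id) {
    sub <- df[as.character(df[[id_column]]) == id, , drop = FALSE]
    start_s <- 0
    if (!is.null(time_column)) {
      tt <- as.numeric(sub[[time_column]])
      sub <- sub[order(tt), , drop = FALSE]
      tt <- sort(tt)
      if (length(tt) > 1L) {
        step <- 1 / sampling_rate_hz
        dt <- diff(tt)
        off <- which(abs(dt - step) > tolerance)
        if (length(off)) {
          abort_sampling(sprintf(
            "non-uniform sampling for participant '%s': step of %g s between rows %d and %d (expected %g s)",
            id, dt[off[1L]], off[1L], off[1L] + 1L, step
          ))
        }
      }
      start_s <- tt[1L]
    }
    physio_series(sub[[value_column]], id,
      start_time_s = start_s, sampling_rate_hz = sampling_rate_hz
    )
  })
  names(out) <- ids
  out
}

#' Read a wide-format session CSV
#'
#' Wide dialect: one `time_s` column plus one numeric column per participant.
#'
#' @inheritParams read_physio_csv
#' @return Named list of `physio_series`.
#' @export
read_session_csv <- function(path, time_column = "time_s",
                             sampling_rate_hz = 1, tolerance = 1e-6) {
  if (!file.exists(path)) {
    abort_input(sprintf("file not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!time_column %in% names(df)) {
    abort_input(sprintf("column '%s' not found in %s", time_column, path))
  }
  tt <- as.numeric(df[[time_column]])
  df <- df[order(tt), , drop = FALSE]
  tt <- sort(tt)
  step <- 1 / sampling_rate_hz
  if (length(tt) > 1L && any(abs(diff(tt) - step) > tolerance)) {
    abort_sampling(sprintf("non-uniform time steps in %s", path))
  }
  ids <- setdiff(names(df), time_column)
  if (!length(ids)) {
    abort_input(sprintf("no participant columns in %s", path))
  }
  out <- lapply(ids, function(id) {
    v <- df[[id]]
    if (!is.numeric(v)) suppressWarnings(v <- as.numeric(v))
    if (anyNA(v) || !all(is.finite(v))) {
      abort_validation(sprintf("non-numeric value in column '%s' of %s", id, path))
    }
    physio_series(v, id, start_time_s = tt[1L], sampling_rate_hz = sampling_rate_hz)
  })
  names(out) <- ids
  out
}

#' Write series to long CSV
#'
#' @param series A `physio_series` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_physio_csv <- function(series, path) {
  if (inherits(series, "physio_series")) series <- list(series)
  df <- dplyr::bind_rows(lapply(series, as_tibble))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Align several series into a session recording
#'
#' Recordings usually start and stop independently (monitors are attached one
#' by one before the session), so a common clock segment has to be carved out
#' before any cross-channel model can be fitted.
#'
#' @param series List of >= 2 `physio_series` with identical sampling rates.
#' @param policy `"intersect"` trims all series to their maximal common time
#'   overlap; `"strict"` errors unless spans are already identical.
#' @param session_id Identifier for the resulting recording.
#' @param episodes Optional [episode_track()] to attach.
#' @return A `session_recording`: participants-by-time matrix on a common
#'   clock plus metadata.
#' @examples
#' a <- physio_series(rnorm(100), "A", start_time_s = 0)
#' b <- physio_series(rnorm(110), "B", start_time_s = 10)
#' rec <- align_session(list(a, b), session_id = "demo")
#' dim(rec$data)
#' @export
align_session <- function(series, policy = c("intersect", "strict"),
                          session_id = "session", episodes = NULL) {
  policy <- match.arg(policy)
  if (!is.list(series) || length(series) < 2L) {
    abort_input("align_session needs a list of at least two physio_series")
  }
  if (!all(vapply(series, inherits, logical(1), "physio_series"))) {
    abort_input("all elements must be physio_series objects")
  }
  rates <- vapply(series, function(s) s$sampling_rate_hz, numeric(1))
  if (length(unique(rates)) != 1L) {
    abort_sampling("sampling rates differ across series")
  }
  rate <- rates[[1L]]
  ids <- vapply(series, function(s) s$participant_id, character(1))
  if (anyDuplicated(ids)) {
    abort_validation("participant ids must be unique")
  }
  starts <- vapply(series, function(s) s$start_time_s, numeric(1))
  ends <- vapply(series, end_time_s, numeric(1))
  if (policy == "strict") {
    if (length(unique(starts)) != 1L || length(unique(ends)) != 1L) {
      abort_alignment("strict alignment requires identical spans")
    }
    lo <- starts[[1L]]
    hi <- ends[[1L]]
  } else {
    lo <- max(starts)
    hi <- min(ends)
    if (hi - lo < 2 / rate) {
      abort_alignment(sprintf(
        "series overlap [%g, %g) s is too short to align", lo, hi
      ))
    }
  }
  n <- floor((hi - lo) * rate + 1e-9)
  rows <- lapply(series, function(s) {
    i0 <- round((lo - s$start_time_s) * rate) + 1L
    s$values[i0:(i0 + n - 1L)]
  })
  data <- do.call(rbind, rows)
  rownames(data) <- ids
  structure(
    list(
      session_id = session_id,
      participant_ids = ids,
      data = data,
      sampling_rate_hz = rate,
      start_time_s = lo,
      episodes = episodes
    ),
    class = "session_recording"
  )
}

#' Construct a session recording from a matrix
#'
#' @param data M x T numeric matrix, rows = participants on a common 1 Hz (or
#'   `sampling_rate_hz`) clock.
#' @param participant_ids Character vector of length M, unique.
#' @param session_id Identifier string.
#' @param sampling_rate_hz Sampling rate.
#' @param start_time_s Time of the first column, seconds from session start.
#' @param episodes Optional [episode_track()].
#' @return A `session_recording`.
#' @export
session_recording <- function(data, participant_ids, session_id = "session",
                              sampling_rate_hz = 1, start_time_s = 0,
                              episodes = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) abort_input("a session needs at least two participants")
  if (length(participant_ids) != nrow(data)) {
    abort_input("participant_ids must match the number of rows")
  }
  if (anyDuplicated(participant_ids)) {
    abort_validation("participant ids must be unique")
  }
  if (!all(is.finite(data))) abort_validation("session data must be finite")
  rownames(data) <- participant_ids
  structure(
    list(
      session_id = session_id,
      participant_ids = as.character(participant_ids),
      data = data,
      sampling_rate_hz = sampling_rate_hz,
      start_time_s = start_time_s,
      episodes = episodes
    ),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> '%s': %d participants (%s), %d samples @ %g Hz\n",
    x$session_id, nrow(x$data), paste(x$participant_ids, collapse = ", "),
    ncol(x$data), x$sampling_rate_hz
  ))
  if (!is.null(x$episodes)) {
    cat(sprintf("  with %d topical episodes\n", nrow(x$episodes)))
  }
  invisible(x)
}

#' @export
as_tibble.session_recording <- function(x, ...) {
  tt <- x$start_time_s + (seq_len(ncol(x$data)) - 1) / x$sampling_rate_hz
  dplyr::bind_rows(lapply(x$participant_ids, function(id) {
    tibble(participant_id = id, time_s = tt, value = x$data[id, ])
  }))
}

#' Write a session recording to wide CSV
#'
#' @param recording A `session_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(recording, path) {
  stopifnot(inherits(recording, "session_recording"))
  tt <- recording$start_time_s +
    (seq_len(ncol(recording$data)) - 1) / recording$sampling_rate_hz
  df <- tibble(time_s = tt)
  for (id in recording$participant_ids) df[[id]] <- recording$data[id, ]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# Episode tracks --------------------------------------------------------------

#' Construct a topical-episode track
#'
#' Topical episodes are human-coded, non-overlapping session segments during
#' which one topic is discussed; synchrony results are aggregated over them.
#' Arbitrary numeric annotation columns (e.g. alliance scores) are carried
#' through untouched.
#'
#' @param df Data frame with columns `episode_id`, `start_s`, `end_s` and
#'   optionally `label` plus numeric annotation columns.
#' @return An `episode_track` tibble, sorted by `start_s`.
#' @export
episode_track <- function(df) {
  df <- as_tibble(df)
  need <- c("episode_id", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_input(sprintf(
      "episode track lacks column(s): %s", paste(miss, collapse = ", ")
    ))
  }
  df$episode_id <- as.character(df$episode_id)
  df$start_s <- as.numeric(df$start_s)
  df$end_s <- as.numeric(df$end_s)
  if (!"label" %in% names(df)) df$label <- df$episode_id
  bad <- which(df$end_s <= df$start_s)
  if (length(bad)) {
    abort_validation(sprintf(
      "episode '%s' has end_s <= start_s", df$episode_id[bad[1L]]
    ))
  }
  df <- dplyr::arrange(df, .data$start_s)
  if (nrow(df) > 1L) {
    overlap <- which(df$start_s[-1L] < df$end_s[-nrow(df)])
    if (length(overlap)) {
      abort_validation(sprintf(
        "episodes '%s' and '%s' overlap",
        df$episode_id[overlap[1L]], df$episode_id[overlap[1L] + 1L]
      ))
    }
  }
  class(df) <- c("episode_track", class(df))
  df
}

#' Read an episode track from CSV or JSON
#'
#' @param path File path; format chosen by extension (`.json` vs CSV).
#' @return An `episode_track`.
#' @export
read_episode_track <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  episode_track(df)
}

#' Write an episode track
#'
#' @param track An `episode_track`.
#' @param path Output path (`.json` or CSV by extension).
#' @return `path`, invisibly.
#' @export
write_episode_track <- function(track, path) {
  df <- as.data.frame(track)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}
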