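#' Leading/pacing count table
#'
#' The machine form of the method's directed count tables: entry
#' `(pacer, leader)` is the number of windows in which the leader's signal
#' significantly leads the pacer's. `unique_sync_windows` counts windows with
#' at least one significant directed pair — a window where several directions
#' are significant is counted once.
#'
#' @param counts M x M integer matrix with participant ids as dimnames (rows
#'   = pacing role, columns = leading role); diagonal ignored (set to 0).
#' @param total_windows Number of windows in the session.
#' @param unique_sync_windows Number of windows with >= 1 significant pair.
#' @return A `sync_table`.
#' @export
sync_table <- function(counts, total_windows, unique_sync_windows) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_input("counts must carry participant ids as dimnames")
  }
  if (!identical(rownames(counts), colnames(counts))) {
    abort_input("counts row and column ids must match")
  }
  diag(counts) <- 0L
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) abort_validation("counts must be non-negative")
  if (unique_sync_windows > total_windows) {
    abort_validation("unique_sync_windows cannot exceed total_windows")
  }
  if (unique_sync_windows > sum(counts)) {
    abort_validation("unique_sync_windows cannot exceed the sum of counts")
  }
  if (any(counts > total_windows)) {
    abort_validation("no directed count can exceed total_windows")
  }
  structure(
    list(
      participant_ids = rownames(counts),
      counts = counts,
      unique_sync_windows = as.integer(unique_sync_windows),
      total_windows = as.integer(total_windows)
    ),
    class = "sync_table"
  )
}

#' @export
print.sync_table <- function(x, ...) {
  cat(sprintf(
    "<sync_table> rows = pacing, cols = leading; %d of %d windows in sync\n",
    x$unique_sync_windows, x$total_windows
  ))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.sync_table <- function(x, ...) {
  as_tibble(x$counts, rownames = "pacer") |>
    pivot_longer(-"pacer", names_to = "leader", values_to = "n_windows") |>
    filter(.data$leader != .data$pacer) |>
    select("leader", "pacer", "n_windows")
}

#' @export
glance.sync_table <- function(x, ...) {
  tibble(
    total_windows = x$total_windows,
    unique_sync_windows = x$unique_sync_windows,
    sum_directed_counts = sum(x$counts),
    pct_session_time = 100 * x$unique_sync_windows / x$total_windows
  )
}

#' Count significant directed windows
#'
#' @param grid A [sync_grid()].
#' @return A [sync_table()]: `counts[pacer, leader]` = number of windows
#'   where that direction is significant; plus unique and total window counts.
#' @export
directed_counts <- function(grid) {
  stopifnot(inherits(grid, "sync_grid"))
  ids <- grid_meta(grid, "participant_ids")
  M <- length(ids)
  counts <- matrix(0L, M, M, dimnames = list(ids, ids))
  sig <- grid[grid$significant, , drop = FALSE]
  if (nrow(sig)) {
    tab <- dplyr::count(as_tibble(sig), .data$pacer, .data$leader)
    counts[cbind(match(tab$pacer, ids), match(tab$leader, ids))] <- tab$n
  }
  sync_table(
    counts,
    total_windows = grid_meta(grid, "total_windows"),
    unique_sync_windows = length(unique(sig$window_index))
  )
}

#' Percent of session time in synchrony
#'
#' With non-overlapping windows that tile the session, the fraction of
#' windows in synchrony is the fraction of session time. `selection = "all"`
#' uses the unique-window convention (a window counts once however many
#' directions are significant); `selection = "pairs"` sums the directed
#' counts of the requested unordered pair(s) — the convention behind per-dyad
#' figures.
#'
#' @param table A [sync_table()].
#' @param selection `"all"` or `"pairs"`.
#' @param pairs For `"pairs"`: character vector of two participant ids (one
#'   dyad) or a list of such vectors.
#' @return Raw percentage (not rounded); see [percent_label()] for the
#'   half-up one-decimal presentation form.
#' @export
session_time_percent <- function(table, selection = c("all", "pairs"),
                                 pairs = NULL) {
  stopifnot(inherits(table, "sync_table"))
  selection <- match.arg(selection)
  if (table$total_windows <= 0) abort_input("total_windows must be positive")
  if (selection == "all") {
    return(100 * table$unique_sync_windows / table$total_windows)
  }
  if (is.null(pairs)) abort_config("selection = 'pairs' needs `pairs`")
  if (!is.list(pairs)) pairs <- list(pairs)
  total <- 0L
  for (pr in pairs) {
    if (length(pr) != 2L || !all(pr %in% table$participant_ids)) {
      abort_config("each pair must name two known participants")
    }
    total <- total + table$counts[pr[1], pr[2]] + table$counts[pr[2], pr[1]]
  }
  100 * total / table$total_windows
}

#' Presentation rounding for percentages
#'
#' Reported percentages are rounded half-up (31.15 prints as 31.2, not the
#' banker's 31.1); integer-valued results print without decimals.
#'
#' @param pct Raw percentage.
#' @param digits Decimal places (default 1).
#' @return Character scalar.
#' @export
percent_label <- function(pct, digits = 1) {
  r <- round_half_up(pct, digits)
  if (r == floor(r)) {
    sprintf("%d%%", as.integer(r))
  } else {
    sprintf(paste0("%.", digits, "f%%"), r)
  }
}

#' Windows with increased synchrony
#'
#' A window shows increased synchrony when more than one of the `M*(M-1)`
#' possible directed synchronizations is significant. The `all_three` flag
#' marks windows in which every unordered pair of participants is linked by
#' at least one significant direction — for a triad, all three people
#' synchronized at once (e.g. mutual synchrony within one dyad plus both of
#' its members leading the third).
#'
#' @param grid A [sync_grid()].
#' @return Tibble: `window_index`, `n_edges`, `edges` (list column of
#'   `"leader->pacer"` strings), `all_three`.
#' @export
increased_ips_windows <- function(grid) {
  stopifnot(inherits(grid, "sync_grid"))
  ids <- grid_meta(grid, "participant_ids")
  sig <- as_tibble(grid[grid$significant, , drop = FALSE])
  if (!nrow(sig)) {
    return(tibble(window_index = integer(), n_edges = integer(),
                  edges = list(), all_three = logical()))
  }
  n_dyads <- length(ids) * (length(ids) - 1L) / 2L
  sig |>
    group_by(.data$window_index) |>
    summarise(
      n_edges = n(),
      edges = list(paste0(.data$leader, "->", .data$pacer)),
      all_three = dplyr::n_distinct(
        paste(pmin(.data$leader, .data$pacer), pmax(.data$leader, .data$pacer))
      ) == n_dyads,
      .groups = "drop"
    ) |>
    filter(.data$n_edges >= 2L)
}

#' Temporal clusters of synchrony windows
#'
#' Synchrony windows tend to group around specific points of a session;
#' clusters are maximal runs of sync windows in which consecutive sync
#' windows are separated by at most `max_gap` non-sync windows.
#'
#' @param grid A [sync_grid()].
#' @param max_gap Allowed gap (in windows) inside a cluster; default 1.
#' @return Tibble: `cluster`, `start_window`, `end_window`, `n_sync_windows`,
#'   `window_indices` (list column).
#' @export
cluster_windows <- function(grid, max_gap = 1L) {
  stopifnot(inherits(grid, "sync_grid"))
  if (max_gap < 0) abort_config("max_gap must be >= 0")
  idx <- sort(unique(grid$window_index[grid$significant]))
  if (!length(idx)) {
    return(tibble(cluster = integer(), start_window = integer(),
                  end_window = integer(), n_sync_windows = integer(),
                  window_indices = list()))
  }
  breaks <- c(0L, which(diff(idx) > max_gap + 1L), length(idx))
  purrr::map(seq_len(length(breaks) - 1L), function(k) {
    members <- idx[(breaks[k] + 1L):breaks[k + 1L]]
    tibble(
      cluster = k,
      start_window = members[1L],
      end_window = members[length(members)],
      n_sync_windows = length(members),
      window_indices = list(members)
    )
  }) |> dplyr::bind_rows()
}

#' Per-episode synchrony summary
#'
#' Each window is assigned to the topical episode containing its midpoint
#' (episodes have arbitrary second boundaries while windows are fixed tiles;
#' the midpoint rule is unambiguous). `pct_episode_time` is
#' `100 * n_sync_windows * window_length_s / episode_duration_s`, capped at
#' 100. Numeric annotation columns on the episode track (e.g. alliance
#' scores) are passed through.
#'
#' @param grid A [sync_grid()].
#' @param episodes An [episode_track()]; defaults to the track attached to
#'   the grid's recording.
#' @return Tibble with one row per episode.
#' @export
episode_summary <- function(grid, episodes = NULL) {
  stopifnot(inherits(grid, "sync_grid"))
  episodes <- episodes %||% grid_meta(grid, "episodes")
  if (is.null(episodes)) abort_input("no episode track supplied or attached")
  episodes <- episode_track(episodes)
  cfg <- grid_meta(grid, "config")
  L <- cfg$window_length_s
  windows <- distinct(as_tibble(grid), .data$window_index, .data$start_s, .data$end_s)
  sync_idx <- unique(grid$window_index[grid$significant])
  mid <- (windows$start_s + windows$end_s) / 2
  ep_of_window <- rep(NA_integer_, nrow(windows))
  for (e in seq_len(nrow(episodes))) {
    inside <- mid >= episodes$start_s[e] & mid < episodes$end_s[e]
    ep_of_window[inside] <- e
  }
  n_out <- sum(is.na(ep_of_window))
  if (n_out > 0L) {
    inform(sprintf(
      "%d window(s) fall outside all episodes and were left unassigned", n_out
    ))
  }
  rows <- purrr::map(seq_len(nrow(episodes)), function(e) {
    w_here <- windows$window_index[which(ep_of_window == e)]
    n_sync <- length(intersect(w_here, sync_idx))
    dur <- episodes$end_s[e] - episodes$start_s[e]
    tibble(
      episode_id = episodes$episode_id[e],
      label = episodes$label[e],
      duration_s = dur,
      n_windows = length(w_here),
      n_sync_windows = n_sync,
      pct_episode_time = min(100, 100 * n_sync * L / dur)
    )
  }) |> dplyr::bind_rows()
  extra <- setdiff(names(episodes),
                   c("episode_id", "start_s", "end_s", "label"))
  if (length(extra)) {
    rows <- left_join(rows,
      select(as_tibble(episodes), "episode_id", all_of(extra)),
      by = "episode_id"
    )
  }
  class(rows) <- c("episode_summary", class(rows))
  rows
}

#' Leading/pacing network summary
#'
#' Column sums of the count table give each participant's windows in a
#' leading role, row sums their windows pacing. The balance index compares
#' the distribution of leading shares to uniform via total-variation
#' distance, normalised so 1 = perfectly equal leading shares and 0 = one
#' participant leads everything.
#'
#' @param table A [sync_table()].
#' @return A `network_summary`: per-participant tibble, directed edge list,
#'   and `balance` in `[0, 1]`.
#' @export
leading_network <- function(table) {
  stopifnot(inherits(table, "sync_table"))
  leading <- colSums(table$counts)
  pacing <- rowSums(table$counts)
  total <- sum(leading)
  M <- length(table$participant_ids)
  if (total == 0) {
    balance <- 1
    inform("all-zero count table: balance defined as 1 (vacuously uniform)")
  } else {
    shares <- leading / total
    tv <- sum(abs(shares - 1 / M)) / 2
    balance <- 1 - tv / (1 - 1 / M)
  }
  edges <- tidy.sync_table(table) |> filter(.data$n_windows > 0)
  structure(
    list(
      participants = tibble(
        participant_id = table$participant_ids,
        windows_leading = as.integer(leading),
        windows_pacing = as.integer(pacing)
      ),
      edges = edges,
      balance = balance,
      total_windows = table$total_windows
    ),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> balance = %.3f\n", x$balance))
  print(x$participants)
  invisible(x)
}

#' @export
tidy.network_summary <- function(x, ...) x$participants

#' @export
glance.network_summary <- function(x, ...) {
  tibble(
    balance = x$balance,
    n_edges = nrow(x$edges),
    total_leading = sum(x$participants$windows_leading)
  )
}

#' Compare two sessions
#'
#' Contrasts the synchrony structure of two sessions of the same participant
#' set: per-direction and total count deltas (both the unique-window and the
#' directed-sum conventions are surfaced, since they answer different
#' questions), network balance change, and a two-proportion chi-square test
#' (without continuity correction) on unique sync windows out of total
#' windows. The chi-square choice is this package's convention for an
#' otherwise descriptive comparison and is labelled as such in the output.
#'
#' @param a,b [sync_grid()]s or [sync_table()]s for the two sessions.
#' @return A `comparison_report`.
#' @export
compare_sessions <- function(a, b) {
  ta <- if (inherits(a, "sync_grid")) directed_counts(a) else a
  tb <- if (inherits(b, "sync_grid")) directed_counts(b) else b
  stopifnot(inherits(ta, "sync_table"), inherits(tb, "sync_table"))
  if (!setequal(ta$participant_ids, tb$participant_ids)) {
    abort_comparison("sessions involve different participant sets")
  }
  ids <- ta$participant_ids
  cb <- tb$counts[ids, ids] # align ordering
  per_pair <- tidy.sync_table(ta) |>
    rename(n_windows_a = "n_windows") |>
    mutate(n_windows_b = cb[cbind(
      match(.data$pacer, ids), match(.data$leader, ids)
    )]) |>
    mutate(
      pct_a = 100 * .data$n_windows_a / ta$total_windows,
      pct_b = 100 * .data$n_windows_b / tb$total_windows,
      delta_windows = .data$n_windows_b - .data$n_windows_a,
      delta_pct = .data$pct_b - .data$pct_a
    )
  pa <- 100 * ta$unique_sync_windows / ta$total_windows
  pb <- 100 * tb$unique_sync_windows / tb$total_windows
  test <- suppressWarnings(stats::prop.test(
    x = c(ta$unique_sync_windows, tb$unique_sync_windows),
    n = c(ta$total_windows, tb$total_windows),
    correct = FALSE
  ))
  na <- leading_network(ta)
  nb <- leading_network(tb)
  structure(
    list(
      per_pair = per_pair,
      totals = tibble(
        convention = c("unique_windows", "directed_sum"),
        a = c(ta$unique_sync_windows, sum(ta$counts)),
        b = c(tb$unique_sync_windows, sum(tb$counts)),
        pct_a = c(pa, 100 * sum(ta$counts) / ta$total_windows),
        pct_b = c(pb, 100 * sum(tb$counts) / tb$total_windows)
      ),
      delta_pct_session_time = pb - pa,
      network_a = na,
      network_b = nb,
      balance_delta = nb$balance - na$balance,
      proportion_test = list(
        statistic = unname(test$statistic),
        # degenerate pooled proportions (0 or 1) make the chi-square NaN;
        # identical proportions carry no evidence either way, so report 1
        p_value = if (is.nan(test$p.value)) 1 else unname(test$p.value),
        method = "two-proportion chi-square without continuity correction (package convention)"
      )
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$totals)
  cat(sprintf(
    "delta %% session time: %+.1f points; balance %0.3f -> %0.3f\n",
    x$delta_pct_session_time, x$network_a$balance, x$network_b$balance
  ))
  cat(sprintf("chi-square p = %.4g (%s)\n",
              x$proportion_test$p_value, x$proportion_test$method))
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) x$per_pair

#' @export
glance.comparison_report <- function(x, ...) {
  tibble(
    delta_pct_session_time = x$delta_pct_session_time,
    balance_a = x$network_a$balance,
    balance_b = x$network_b$balance,
    balance_delta = x$balance_delta,
    chisq_p_value = x$proportion_test$p_value
  )
}
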