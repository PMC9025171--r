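#' Define a synthetic session scenario
#'
#' Scenarios generate arousal-like multichannel sessions with known
#' ground-truth coupling: piecewise vector-autoregressive dynamics (segments
#' tile the session; coupling can switch abruptly at boundaries), optional
#' slow per-channel trends (arousal typically drifts over a session), and an
#' optional positivity transform mimicking a non-negative arousal index.
#' Directionality ground truth is defined on the latent VAR, before trend
#' and transform.
#'
#' @param segments List of segments, each
#'   `list(start_s, end_s, coupling = list(A_1, ..., A_p))` with M x M lag
#'   coefficient matrices; segments must tile `[0, duration_s)` and each
#'   segment's companion matrix must have spectral radius < 1.
#' @param duration_s Session length, seconds.
#' @param participant_ids Channel ids (M >= 2).
#' @param innovation_sd Innovation standard deviation, length 1 or M.
#' @param trend `NULL`, or a list of per-channel specs
#'   `list(type = "linear", offset =, slope =)` or
#'   `list(type = "exp_decay", offset =, rate =)` (offset added at t = 0,
#'   decaying at `rate` per second).
#' @param positivity_transform `"none"` or `"softplus_shift"`
#'   (`log(1 + exp(x + 4))`, strictly positive, near-linear in the typical
#'   signal range).
#' @param sampling_rate_hz Sampling rate (1 Hz).
#' @param rng_seed Seed; data and ground truth are jointly reproducible.
#' @return A `simulation_scenario`.
#' @export
simulation_scenario <- function(segments, duration_s,
                                participant_ids = c("P1", "P2", "P3"),
                                innovation_sd = 1,
                                trend = NULL,
                                positivity_transform = c("none", "softplus_shift"),
                                sampling_rate_hz = 1,
                                rng_seed = 1L) {
  positivity_transform <- match.arg(positivity_transform)
  M <- length(participant_ids)
  if (M < 2L) abort_config("a scenario needs at least two participants")
  if (length(innovation_sd) == 1L) innovation_sd <- rep(innovation_sd, M)
  if (length(innovation_sd) != M || any(innovation_sd <= 0)) {
    abort_config("innovation_sd must be positive, length 1 or M")
  }
  if (!length(segments)) abort_config("segments must be non-empty")
  starts <- vapply(segments, function(s) s$start_s, numeric(1))
  ends <- vapply(segments, function(s) s$end_s, numeric(1))
  o <- order(starts)
  segments <- segments[o]
  starts <- starts[o]
  ends <- ends[o]
  if (starts[1L] != 0 || ends[length(ends)] != duration_s ||
      (length(starts) > 1L && any(starts[-1L] != ends[-length(ends)]))) {
    abort_config("segments must tile [0, duration_s) without gaps or overlap")
  }
  for (s in segments) {
    for (A in s$coupling) {
      if (!is.matrix(A) || any(dim(A) != M)) {
        abort_config("each coupling matrix must be M x M")
      }
    }
    if (companion_spectral_radius(s$coupling) >= 1) {
      abort_config(
        "unstable coupling: companion spectral radius >= 1 in a segment",
        class = "pdcsync_scenario_error"
      )
    }
  }
  if (!is.null(trend) && length(trend) != M) {
    abort_config("trend must be NULL or a list with one spec per channel")
  }
  structure(
    list(
      participant_ids = participant_ids,
      duration_s = duration_s,
      sampling_rate_hz = sampling_rate_hz,
      segments = segments,
      innovation_sd = innovation_sd,
      trend = trend,
      positivity_transform = positivity_transform,
      rng_seed = as.integer(rng_seed)
    ),
    class = "simulation_scenario"
  )
}

companion_spectral_radius <- function(coeffs) {
  p <- length(coeffs)
  if (p == 0L) return(0)
  M <- nrow(coeffs[[1L]])
  comp <- matrix(0, M * p, M * p)
  for (r in seq_len(p)) comp[1:M, ((r - 1) * M + 1):(r * M)] <- coeffs[[r]]
  if (p > 1L) {
    comp[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "<simulation_scenario> %d channels, %g s, %d segment(s), transform: %s\n",
    length(x$participant_ids), x$duration_s, length(x$segments),
    x$positivity_transform
  ))
  invisible(x)
}

#' Simulate one stationary VAR segment
#'
#' Runs the recursion `x(t) = sum_r A_r x(t-r) + e(t)` with Gaussian
#' innovations, consuming the current RNG stream. With `init = NULL` a
#' burn-in of `10 * order` samples is generated and discarded; otherwise
#' `init` (M x p, most recent sample in the last column) seeds the recursion
#' so state carries across segment boundaries.
#'
#' @param coupling List of M x M lag coefficient matrices `A_1..A_p`.
#' @param n Number of samples to return.
#' @param innovation_sd Innovation sd, length 1 or M.
#' @param init Optional M x p matrix of initial lagged values.
#' @return M x n numeric matrix.
#' @export
simulate_var_segment <- function(coupling, n, innovation_sd = 1, init = NULL) {
  p <- length(coupling)
  if (p < 1L) abort_config("coupling must contain at least one lag matrix")
  M <- nrow(coupling[[1L]])
  if (companion_spectral_radius(coupling) >= 1) {
    abort_config("unstable coefficients: spectral radius >= 1",
                 class = "pdcsync_scenario_error")
  }
  if (length(innovation_sd) == 1L) innovation_sd <- rep(innovation_sd, M)
  burn <- if (is.null(init)) 10L * p else 0L
  total <- n + burn
  x <- matrix(0, M, total + p)
  if (!is.null(init)) {
    if (!is.matrix(init) || nrow(init) != M || ncol(init) != p) {
      abort_config("init must be an M x p matrix")
    }
    x[, seq_len(p)] <- init
  }
  e <- matrix(stats::rnorm(M * total, sd = innovation_sd), M, total)
  for (t in seq_len(total)) {
    col <- p + t
    acc <- e[, t]
    for (r in seq_len(p)) {
      acc <- acc + coupling[[r]] %*% x[, col - r]
    }
    x[, col] <- acc
  }
  x[, (p + burn + 1L):(p + total), drop = FALSE]
}

#' Simulate a full session from a scenario
#'
#' Concatenates segment simulations (VAR state carried across boundaries),
#' adds per-channel trend, applies the positivity transform, and packages the
#' result as a [session_recording()].
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `recording` (a `session_recording`) and `scenario` (the
#'   scenario, for ground-truth labelling via [ground_truth_windows()]).
#' @export
simulate_session <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$rng_seed)
  rate <- scenario$sampling_rate_hz
  M <- length(scenario$participant_ids)
  pieces <- vector("list", length(scenario$segments))
  init <- NULL
  for (k in seq_along(scenario$segments)) {
    seg <- scenario$segments[[k]]
    n_k <- as.integer(round((seg$end_s - seg$start_s) * rate))
    pieces[[k]] <- simulate_var_segment(seg$coupling, n_k,
                                        scenario$innovation_sd, init = init)
    p_next <- if (k < length(scenario$segments)) {
      length(scenario$segments[[k + 1L]]$coupling)
    } else {
      0L
    }
    if (p_next > 0L) {
      have <- pieces[[k]]
      init <- have[, (ncol(have) - p_next + 1L):ncol(have), drop = FALSE]
    }
  }
  data <- do.call(cbind, pieces)
  if (!is.null(scenario$trend)) {
    tt <- (seq_len(ncol(data)) - 1) / rate
    for (m in seq_len(M)) {
      tr <- scenario$trend[[m]]
      if (is.null(tr)) next
      data[m, ] <- data[m, ] + switch(tr$type,
        linear = (tr$offset %||% 0) + (tr$slope %||% 0) * tt,
        exp_decay = (tr$offset %||% 0) * exp(-(tr$rate %||% 0) * tt),
        abort_config(sprintf("unknown trend type '%s'", tr$type))
      )
    }
  }
  if (scenario$positivity_transform == "softplus_shift") {
    data <- log1p(exp(data + 4))
  }
  rec <- session_recording(
    data, scenario$participant_ids,
    session_id = sprintf("sim-%d", scenario$rng_seed),
    sampling_rate_hz = rate
  )
  list(recording = rec, scenario = scenario)
}

# Directed edges (leader -> pacer) implied by a segment's lag matrices.
segment_edges <- function(coupling, ids) {
  M <- length(ids)
  has_edge <- matrix(FALSE, M, M)
  for (A in coupling) has_edge <- has_edge | (A != 0)
  diag(has_edge) <- FALSE
  idx <- which(has_edge, arr.ind = TRUE)
  if (!nrow(idx)) return(character())
  # A[i, j] != 0 means channel j drives channel i: j leads, i paces
  paste0(ids[idx[, "col"]], "->", ids[idx[, "row"]])
}

#' Ground-truth window labels for a scenario
#'
#' For a given window length, labels each window with the directed edges of
#' the segment that fully contains it. Windows straddling a segment boundary
#' are flagged `mixed` and should be excluded when scoring recovery.
#'
#' @param scenario A [simulation_scenario()].
#' @param window_length_s Window length in seconds.
#' @return Tibble: `window_index` (0-based), `start_s`, `end_s`, `edges`
#'   (list column of `"leader->pacer"` strings), `coupled`, `mixed`.
#' @export
ground_truth_windows <- function(scenario, window_length_s = 50) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n_win <- floor(scenario$duration_s / window_length_s)
  ids <- scenario$participant_ids
  seg_start <- vapply(scenario$segments, function(s) s$start_s, numeric(1))
  seg_end <- vapply(scenario$segments, function(s) s$end_s, numeric(1))
  purrr::map(seq_len(n_win) - 1L, function(w) {
    w0 <- w * window_length_s
    w1 <- w0 + window_length_s
    inside <- which(seg_start <= w0 & seg_end >= w1)
    if (length(inside)) {
      eg <- segment_edges(scenario$segments[[inside[1L]]]$coupling, ids)
      tibble(window_index = w, start_s = w0, end_s = w1,
             edges = list(eg), coupled = length(eg) > 0, mixed = FALSE)
    } else {
      tibble(window_index = w, start_s = w0, end_s = w1,
             edges = list(character()), coupled = NA, mixed = TRUE)
    }
  }) |> dplyr::bind_rows()
}

#' Catalogue of standard scenarios
#'
#' Named building blocks used by the tests, the calibration procedure and
#' the worked examples:
#' \describe{
#'   \item{null_triad}{three independent AR(1) channels (self-coefficient
#'     0.5), no trends — the type-I-error reference.}
#'   \item{unidirectional}{as null, plus channel 1 driving channel 2 at lag 1
#'     with coefficient `strength` for the whole session.}
#'   \item{mutual}{bidirectional coupling (0.35 each way) between channels 1
#'     and 2; channel 3 independent.}
#'   \item{triad_cascade}{channels 1 and 2 each drive channel 3 (0.4).}
#'   \item{nonstationary_null}{independent channels with strong opposing
#'     linear trends (±0.005 units/s) — a false-positive stress test for
#'     drifting arousal.}
#' }
#' All default to 3 channels, 2500 s at 1 Hz (50 windows of 50 s), unit
#' innovation sd, and the softplus positivity transform off so the latent
#' VAR is observed directly; pass the scenarios through
#' [simulation_scenario()] fields to change that.
#'
#' @param strength Coupling coefficient for `unidirectional`.
#' @param duration_s Session length, seconds.
#' @param rng_seed Seed stored in each scenario.
#' @return Named list of [simulation_scenario()]s.
#' @export
standard_scenarios <- function(strength = 0.6, duration_s = 2500,
                               rng_seed = 1L) {
  M <- 3L
  base <- function(A1) {
    list(list(start_s = 0, end_s = duration_s, coupling = list(A1)))
  }
  d <- diag(0.5, M)
  uni <- d
  uni[2, 1] <- strength
  mut <- d
  mut[1, 2] <- 0.35
  mut[2, 1] <- 0.35
  casc <- d
  casc[3, 1] <- 0.4
  casc[3, 2] <- 0.4
  trend <- list(
    list(type = "linear", offset = 0, slope = 0.005),
    list(type = "linear", offset = 0, slope = -0.005),
    list(type = "linear", offset = 0, slope = 0)
  )
  list(
    null_triad = simulation_scenario(base(d), duration_s, rng_seed = rng_seed),
    unidirectional = simulation_scenario(base(uni), duration_s,
                                         rng_seed = rng_seed),
    mutual = simulation_scenario(base(mut), duration_s, rng_seed = rng_seed),
    triad_cascade = simulation_scenario(base(casc), duration_s,
                                        rng_seed = rng_seed),
    nonstationary_null = simulation_scenario(base(d), duration_s,
                                             trend = trend,
                                             rng_seed = rng_seed)
  )
}

#' Write a simulated session with its ground truth
#'
#' The session goes to the wide CSV dialect; the scenario's ground-truth
#' window labels (for the given window length) go to a JSON sidecar.
#'
#' @param sim Result of [simulate_session()].
#' @param csv_path Output CSV path; sidecar is `<csv_path>.truth.json`.
#' @param window_length_s Window length for the ground-truth labels.
#' @return `csv_path`, invisibly.
#' @export
write_simulated_session <- function(sim, csv_path, window_length_s = 50) {
  write_session_csv(sim$recording, csv_path)
  truth <- ground_truth_windows(sim$scenario, window_length_s)
  truth$edges <- purrr::map(truth$edges, as.list)
  jsonlite::write_json(
    list(window_length_s = window_length_s,
         rng_seed = sim$scenario$rng_seed,
         windows = truth),
    paste0(csv_path, ".truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(csv_path)
}
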