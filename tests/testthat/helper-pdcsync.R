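# Shared test helpers: independent oracles and small object builders.

# Independent brute-force PDC evaluation: explicit elementwise complex
# arithmetic, deliberately written as plain loops so it shares no code path
# with pdc_spectrum().
brute_force_pdc <- function(coeffs, freqs) {
  M <- nrow(coeffs[[1L]])
  p <- length(coeffs)
  out <- array(0, c(length(freqs), M, M))
  for (k in seq_along(freqs)) {
    A <- diag(M) + 0i
    for (r in seq_len(p)) {
      phase <- exp(-1i * 2 * pi * freqs[k] * r)
      for (i in seq_len(M)) {
        for (j in seq_len(M)) {
          A[i, j] <- A[i, j] - coeffs[[r]][i, j] * phase
        }
      }
    }
    for (j in seq_len(M)) {
      d <- sqrt(sum(Mod(A[, j])^2))
      for (i in seq_len(M)) out[k, i, j] <- Mod(A[i, j]) / d
    }
  }
  out
}

# Wrap raw coefficient matrices as a fitted-model object.
as_mvar_model <- function(coeffs, labels = NULL) {
  M <- nrow(coeffs[[1L]])
  labels <- labels %||% paste0("ch", seq_len(M))
  structure(
    list(channel_labels = labels, order_p = length(coeffs), coeffs = coeffs,
         resid_cov = diag(M), n_samples = 1000L, standardized = TRUE),
    class = "mvar_model"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# Random MVAR coefficients, scaled to modest magnitude (spectrum evaluation
# does not require stationarity, only non-degenerate columns).
random_coeffs <- function(M, p) {
  lapply(seq_len(p), function(r) matrix(stats::rnorm(M * M, sd = 0.3), M, M))
}

# Tiny hand-built grid: edges is a data.frame(window_index, leader, pacer).
tiny_grid <- function(edges, total_windows, ids = c("A", "B", "C"),
                      episodes = NULL) {
  pairs <- expand.grid(leader = ids, pacer = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$leader != pairs$pacer, ]
  full <- tidyr::crossing(window_index = 0:(total_windows - 1L),
                          tibble::as_tibble(pairs))
  edges$significant <- rep(TRUE, nrow(edges))
  res <- dplyr::left_join(full, edges, by = c("window_index", "leader", "pacer"))
  res$significant <- !is.na(res$significant)
  res$start_s <- res$window_index * 50
  res$end_s <- res$start_s + 50
  res$stat <- ifelse(res$significant, 0.5, 0.05)
  res$p_value <- ifelse(res$significant, 0.001, 0.6)
  sync_grid(res, session_id = "tiny", participant_ids = ids,
            config = analysis_config(n_surrogates = 999),
            total_windows = total_windows, episodes = episodes)
}
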