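#' Analysis configuration
#'
#' Bundles every tunable of the windowed synchrony pipeline. Defaults follow
#' the method's reference setup: 50 s non-overlapping windows, 1000 surrogate
#' iterations per window and pair, significance threshold alpha divided by a
#' correction divisor of 3 (the number of comparisons the same pair of
#' signals participates in), circular-shift surrogates, per-window channel
#' standardisation, BIC order selection up to order 6, and the max reducer
#' over the full (0, 0.5] band on a 64-point frequency grid.
#'
#' @param window_length_s Window length, seconds (>= 10).
#' @param window_overlap_s Overlap between consecutive windows, seconds.
#' @param n_surrogates Monte-Carlo surrogate count per test (>= 19).
#' @param alpha Nominal significance level in (0, 1).
#' @param correction_divisor Positive integer; the threshold applied is
#'   `alpha / correction_divisor`.
#' @param surrogate_method `"circular_shift"` or `"phase_randomize"`.
#' @param reducer Frequency reducer for the per-direction statistic.
#' @param band Frequency band, sub-interval of (0, 0.5] cycles/sample.
#' @param n_freqs Frequency grid size.
#' @param order MVAR order: `"bic"`/`"aic"` for per-window selection or a
#'   fixed positive integer.
#' @param max_order Cap for order selection.
#' @param standardize Per-window channel standardisation flag.
#' @param rng_seed Master seed; every (window, pair) surrogate stream is
#'   derived from it by stable hashing, so reruns are bit-identical.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(window_length_s = 50,
                            window_overlap_s = 0,
                            n_surrogates = 1000L,
                            alpha = 0.05,
                            correction_divisor = 3L,
                            surrogate_method = c("circular_shift", "phase_randomize"),
                            reducer = c("max", "mean"),
                            band = c(0, 0.5),
                            n_freqs = 64L,
                            order = "bic",
                            max_order = 6L,
                            standardize = TRUE,
                            rng_seed = 1L) {
  surrogate_method <- match.arg(surrogate_method)
  reducer <- match.arg(reducer)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_config("alpha must lie strictly between 0 and 1")
  }
  if (!is_scalar_number(window_length_s) || window_length_s < 10) {
    abort_config("window_length_s must be at least 10 s")
  }
  if (window_overlap_s < 0 || window_overlap_s >= window_length_s) {
    abort_config("window_overlap_s must be in [0, window_length_s)")
  }
  if (!is_scalar_number(n_surrogates) || n_surrogates < 19) {
    abort_config("n_surrogates must be at least 19")
  }
  if (!is_scalar_number(correction_divisor) || correction_divisor < 1) {
    abort_config("correction_divisor must be a positive integer")
  }
  if (is.character(order)) {
    order <- match.arg(order, c("bic", "aic"))
  } else if (!is_scalar_number(order) || order < 1) {
    abort_config("order must be 'bic', 'aic', or a positive integer")
  }
  if (length(band) != 2L || band[1] < 0 || band[2] > 0.5 || band[1] >= band[2]) {
    abort_config("band must be an interval inside (0, 0.5]")
  }
  structure(
    list(
      window_length_s = window_length_s,
      window_overlap_s = window_overlap_s,
      n_surrogates = as.integer(n_surrogates),
      alpha = alpha,
      correction_divisor = as.integer(correction_divisor),
      surrogate_method = surrogate_method,
      reducer = reducer,
      band = as.numeric(band),
      n_freqs = as.integer(n_freqs),
      order = order,
      max_order = as.integer(max_order),
      standardize = isTRUE(standardize),
      rng_seed = as.integer(rng_seed)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  window: %g s (overlap %g s)\n", x$window_length_s, x$window_overlap_s))
  cat(sprintf("  surrogates: %d (%s), threshold %g/%d = %g\n",
              x$n_surrogates, x$surrogate_method, x$alpha,
              x$correction_divisor, x$alpha / x$correction_divisor))
  cat(sprintf("  statistic: %s over (%g, %g], %d-point grid, order = %s (max %d)\n",
              x$reducer, x$band[1], x$band[2], x$n_freqs,
              as.character(x$order), x$max_order))
  cat(sprintf("  standardize: %s, seed: %d\n", x$standardize, x$rng_seed))
  invisible(x)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys error; missing keys take the [analysis_config()] defaults.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_config(sprintf(
      "unknown configuration key(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  do.call(analysis_config, vals)
}
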