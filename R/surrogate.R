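#' Generate one surrogate segment
#'
#' Surrogates preserve each channel's own structure while destroying the
#' cross-channel alignment under test, building the Monte-Carlo null for the
#' per-window PDC statistic.
#'
#' `circular_shift` (default) rotates every channel after the first by an
#' independent uniform offset in `[min_shift + 1, n - min_shift - 1]`; each
#' channel keeps its exact marginal distribution and autocorrelation (up to
#' the wrap-around point), which matters for slowly varying arousal signals.
#' `phase_randomize` replaces each channel's Fourier phases with independent
#' uniform draws (amplitude spectrum preserved; stationarity assumed).
#'
#' Both methods consume the current RNG stream: seed beforehand for
#' reproducibility.
#'
#' @param segment M x n numeric matrix (rows = channels).
#' @param method `"circular_shift"` or `"phase_randomize"`.
#' @param min_shift Exclusion zone at both ends of the rotation range, in
#'   samples; set to the MVAR order so no surrogate is a near-identity shift
#'   within the model's lag span.
#' @return An M x n matrix.
#' @export
make_surrogate <- function(segment, method = c("circular_shift", "phase_randomize"),
                           min_shift = 1L) {
  method <- match.arg(method)
  segment <- as.matrix(segment)
  n <- ncol(segment)
  M <- nrow(segment)
  if (n < 4L) abort_config("segment too short for surrogate generation")
  out <- segment
  if (method == "circular_shift") {
    lo <- as.integer(min_shift) + 1L
    hi <- n - as.integer(min_shift) - 1L
    if (hi < lo) {
      abort_config(sprintf(
        "segment of %d samples too short for circular shifts with min_shift %d",
        n, min_shift
      ))
    }
    for (m in seq_len(M)[-1L]) {
      k <- if (hi == lo) lo else sample(lo:hi, 1L)
      idx <- ((seq_len(n) - 1L + k) %% n) + 1L
      out[m, ] <- segment[m, idx]
    }
  } else {
    for (m in seq_len(M)) {
      out[m, ] <- phase_randomize_channel(segment[m, ])
    }
  }
  out
}

# Phase-randomise one channel, keeping the amplitude spectrum and realness.
phase_randomize_channel <- function(x) {
  n <- length(x)
  z <- stats::fft(x)
  half <- floor((n - 1) / 2)
  if (half >= 1) {
    ph <- stats::runif(half, 0, 2 * pi)
    idx <- 2:(half + 1)
    z[idx] <- Mod(z[idx]) * exp(1i * ph)
    z[n + 2 - idx] <- Conj(z[idx])
  }
  # DC (and Nyquist when n is even) stay real
  Re(stats::fft(z, inverse = TRUE)) / n
}
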