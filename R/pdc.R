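#' Partial Directed Coherence spectrum of a fitted MVAR model
#'
#' Partial Directed Coherence is a frequency-domain formulation of Granger
#' causality. From the MVAR coefficient matrices it forms
#' \deqn{\bar{A}(f) = I - \sum_{r=1}^{p} A_r e^{-i 2 \pi f r}}
#' and the directed coherence from channel j (the leader) into channel i
#' (the pacer)
#' \deqn{|\pi_{i \leftarrow j}(f)| = |\bar{A}_{ij}(f)| /
#'   \sqrt{\sum_k |\bar{A}_{kj}(f)|^2},}
#' the classic column-normalised magnitude form. Each source column therefore
#' satisfies \eqn{\sum_i |\pi_{i \leftarrow j}(f)|^2 = 1} at every frequency.
#'
#' @param model An [fit_mvar()] result.
#' @param n_freqs Number of grid points; the grid is `k/(2*n_freqs)` for
#'   `k = 1..n_freqs`, i.e. normalised frequencies in (0, 0.5] cycles/sample
#'   (at 1 Hz sampling: cycles/second, so 0.5 is the Nyquist frequency).
#' @return A `pdc_spectrum`: `freqs` (length K) and `values`, a K x M x M
#'   array with `values[f, i, j]` = \eqn{|\pi_{i \leftarrow j}(f)|}.
#' @examples
#' m <- fit_mvar(matrix(rnorm(600), 2, 300), order_p = 1)
#' sp <- pdc_spectrum(m, n_freqs = 16)
#' apply(sp$values^2, c(1, 3), sum) # all 1: column normalisation
#' @export
pdc_spectrum <- function(model, n_freqs = 64L) {
  stopifnot(inherits(model, "mvar_model"))
  if (n_freqs < 2L) abort_config("n_freqs must be >= 2")
  M <- length(model$channel_labels)
  p <- model$order_p
  freqs <- seq_len(n_freqs) / (2 * n_freqs)
  # Abar(f) entrywise over the whole grid in one complex matmul:
  # rows = frequencies, columns = vec(A) entries (column-major i,j)
  coef_flat <- matrix(unlist(model$coeffs), nrow = M * M) # (M^2) x p
  E <- exp(-2i * pi * outer(freqs, seq_len(p)))           # K x p
  Abar_flat <- -(E %*% t(coef_flat))                      # K x M^2
  eye_flat <- as.vector(diag(M))
  Abar_flat <- sweep(Abar_flat, 2L, eye_flat, "+")
  mags2 <- Mod(Abar_flat)^2
  dim(mags2) <- c(n_freqs, M, M)
  denom2 <- apply(mags2, c(1L, 3L), sum) # K x M, per source column j
  if (any(denom2 < .Machine$double.eps^2)) {
    k_bad <- which(denom2 < .Machine$double.eps^2, arr.ind = TRUE)[1L, 1L]
    abort_numeric(sprintf(
      "degenerate model: all-zero column of Abar at frequency %g", freqs[k_bad]
    ))
  }
  values <- sqrt(mags2 / aperm(array(denom2, c(n_freqs, M, M)), c(1L, 3L, 2L)))
  dimnames(values) <- list(NULL, model$channel_labels, model$channel_labels)
  structure(
    list(freqs = freqs, values = values, channel_labels = model$channel_labels,
         source_model = model),
    class = "pdc_spectrum"
  )
}

#' @export
print.pdc_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pdc_spectrum> %d frequencies x %d channels (%s)\n",
    length(x$freqs), length(x$channel_labels),
    paste(x$channel_labels, collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.pdc_spectrum <- function(x, ...) {
  M <- length(x$channel_labels)
  grid <- expand.grid(
    f = seq_along(x$freqs), i = seq_len(M), j = seq_len(M),
    KEEP.OUT.ATTRS = FALSE
  )
  tibble(
    freq = x$freqs[grid$f],
    leader = x$channel_labels[grid$j],
    pacer = x$channel_labels[grid$i],
    magnitude = x$values[cbind(grid$f, grid$i, grid$j)]
  ) |>
    arrange(.data$leader, .data$pacer, .data$freq)
}

#' Directed pair
#'
#' One direction of a pair: the leader's past is tested for improving the
#' prediction of the pacer's present.
#'
#' @param leader,pacer Participant/channel identifiers; must differ.
#' @return A `directed_pair`.
#' @export
directed_pair <- function(leader, pacer) {
  if (identical(leader, pacer)) {
    abort_validation("leader and pacer must differ")
  }
  structure(list(leader = as.character(leader), pacer = as.character(pacer)),
            class = "directed_pair")
}

#' @export
print.directed_pair <- function(x, ...) {
  cat(sprintf("<directed_pair> %s -> %s\n", x$leader, x$pacer))
  invisible(x)
}

#' Scalar per-direction PDC statistic
#'
#' Reduces the squared PDC magnitude for one direction over a frequency band
#' to a single number in `[0, 1]` — the per-window detection statistic fed to
#' the surrogate test. The default `max` reducer is sensitive to narrowband
#' coupling; `mean` averages over the band.
#'
#' @param spectrum A [pdc_spectrum()].
#' @param pair A [directed_pair()] (labels must be channels of the spectrum).
#' @param band Length-2 numeric, a sub-interval of (0, 0.5]; at least one grid
#'   frequency must fall inside.
#' @param reducer `"max"` or `"mean"`.
#' @return A number in `[0, 1]`.
#' @export
pdc_statistic <- function(spectrum, pair, band = c(0, 0.5),
                          reducer = c("max", "mean")) {
  stopifnot(inherits(spectrum, "pdc_spectrum"), inherits(pair, "directed_pair"))
  reducer <- match.arg(reducer)
  i <- match(pair$pacer, spectrum$channel_labels)
  j <- match(pair$leader, spectrum$channel_labels)
  if (is.na(i) || is.na(j)) {
    abort_config("pair labels not found among spectrum channels")
  }
  sel <- spectrum$freqs > band[1] & spectrum$freqs <= band[2]
  if (!any(sel)) {
    abort_config("no grid frequency inside the requested band")
  }
  vals <- spectrum$values[sel, i, j]^2
  if (reducer == "max") max(vals) else mean(vals)
}
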