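#' Fit a multivariate autoregressive model by least squares
#'
#' Fits the order-p vector autoregression
#' \deqn{x(t) = \sum_{r=1}^{p} A_r x(t-r) + e(t)}
#' to a short window of the session by ordinary least squares on stacked lag
#' regressors. The fit is deterministic; no intercept is included (channels
#' are centred when `standardize = TRUE`, the default path in the pipeline).
#'
#' @param segment M x n numeric matrix, rows = channels, columns = samples.
#' @param order_p Model order p >= 1.
#' @param standardize Centre and scale each channel to unit variance within
#'   the segment before fitting. Makes the downstream coherence statistic
#'   invariant to per-channel unit changes; a zero-variance channel errors.
#' @return An `mvar_model` with coefficient matrices `coeffs` (list of
#'   `A_1..A_p`, entry `[i, j]` = influence of channel j at that lag on
#'   channel i), residual covariance `resid_cov`, and fit metadata.
#' @examples
#' x <- matrix(rnorm(400), 2, 200)
#' m <- fit_mvar(x, order_p = 1)
#' m$coeffs[[1]]
#' @export
fit_mvar <- function(segment, order_p, standardize = TRUE) {
  segment <- as.matrix(segment)
  M <- nrow(segment)
  n <- ncol(segment)
  p <- as.integer(order_p)
  if (p < 1L) abort_config("order_p must be >= 1")
  if (!all(is.finite(segment))) abort_input("segment contains non-finite values")
  if (n <= M * p + p) {
    abort_fit(sprintf(
      "window of %d samples is too short for %d channels at order %d", n, M, p
    ))
  }
  if (standardize) {
    sds <- apply(segment, 1L, stats::sd)
    if (any(sds == 0 | !is.finite(sds))) {
      abort_degenerate(sprintf(
        "zero-variance channel '%s' in segment",
        (rownames(segment) %||% as.character(seq_len(M)))[which(sds == 0)[1L]]
      ))
    }
    segment <- (segment - rowMeans(segment)) / sds
  }
  labels <- rownames(segment) %||% paste0("ch", seq_len(M))

  Y <- t(segment)                       # n x M
  resp <- Y[(p + 1L):n, , drop = FALSE] # (n - p) x M
  X <- matrix(0, n - p, M * p)
  for (r in seq_len(p)) {
    X[, ((r - 1L) * M + 1L):(r * M)] <- Y[(p + 1L - r):(n - r), , drop = FALSE]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort_fit("rank-deficient lag regressor matrix; channels are collinear")
  }
  B <- qr.coef(qx, resp)                # (M p) x M
  resid <- resp - X %*% B
  sigma <- crossprod(resid) / nrow(resid)
  coeffs <- lapply(seq_len(p), function(r) {
    A <- t(B[((r - 1L) * M + 1L):(r * M), , drop = FALSE])
    dimnames(A) <- list(labels, labels)
    A
  })
  dimnames(sigma) <- list(labels, labels)
  structure(
    list(
      channel_labels = labels,
      order_p = p,
      coeffs = coeffs,
      resid_cov = sigma,
      n_samples = n,
      standardized = standardize
    ),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf(
    "<mvar_model> %d channels (%s), order %d, fitted on %d samples\n",
    length(x$channel_labels), paste(x$channel_labels, collapse = ", "),
    x$order_p, x$n_samples
  ))
  invisible(x)
}

#' @export
tidy.mvar_model <- function(x, ...) {
  purrr::imap(x$coeffs, function(A, r) {
    as_tibble(A, rownames = "to") |>
      pivot_longer(-"to", names_to = "from", values_to = "estimate") |>
      mutate(lag = r, .before = 1L)
  }) |>
    dplyr::bind_rows() |>
    select("lag", "from", "to", "estimate")
}

#' @export
glance.mvar_model <- function(x, ...) {
  M <- length(x$channel_labels)
  n_eff <- x$n_samples - x$order_p
  ld <- determinant(x$resid_cov, logarithm = TRUE)$modulus[[1]]
  k <- M^2 * x$order_p
  tibble(
    n_channels = M, order_p = x$order_p, n_samples = x$n_samples,
    logdet_sigma = ld,
    aic = n_eff * ld + 2 * k,
    bic = n_eff * ld + log(n_eff) * k
  )
}

# Information criterion for one candidate order on a fixed subsample.
ic_for_order <- function(Y, p, max_order, criterion) {
  n <- nrow(Y)
  M <- ncol(Y)
  resp <- Y[(max_order + 1L):n, , drop = FALSE]
  n_eff <- nrow(resp)
  X <- matrix(0, n_eff, M * p)
  for (r in seq_len(p)) {
    X[, ((r - 1L) * M + 1L):(r * M)] <-
      Y[(max_order + 1L - r):(n - r), , drop = FALSE]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NA_real_)
  resid <- resp - X %*% qr.coef(qx, resp)
  sigma <- crossprod(resid) / n_eff
  ld <- determinant(sigma, logarithm = TRUE)
  if (ld$sign <= 0) return(NA_real_)
  k <- M^2 * p
  pen <- if (criterion == "aic") 2 else log(n_eff)
  ld$modulus[[1]] * n_eff + pen * k
}

#' Select the MVAR order by information criterion
#'
#' Fits candidate orders `1..max_order` on the common subsample
#' `t = max_order+1..n` (so criteria are comparable across orders) and returns
#' the order minimising AIC or BIC; ties break toward the smaller order.
#' `max_order` is silently capped so that every candidate satisfies the
#' least-squares identifiability condition `n > M*p + p`.
#'
#' @inheritParams fit_mvar
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param max_order Largest order to consider.
#' @return The selected order, a positive integer.
#' @export
select_order <- function(segment, criterion = c("bic", "aic"), max_order = 6L,
                         standardize = TRUE) {
  criterion <- match.arg(criterion)
  segment <- as.matrix(segment)
  M <- nrow(segment)
  n <- ncol(segment)
  if (max_order < 1L) abort_config("max_order must be >= 1")
  feasible <- floor((n - 1) / (M + 1))
  max_order <- min(as.integer(max_order), feasible)
  if (max_order < 1L) {
    abort_fit(sprintf("no feasible order for %d samples and %d channels", n, M))
  }
  if (standardize) {
    sds <- apply(segment, 1L, stats::sd)
    if (any(sds == 0 | !is.finite(sds))) {
      abort_degenerate("zero-variance channel in segment")
    }
    segment <- (segment - rowMeans(segment)) / sds
  }
  Y <- t(segment)
  ic <- vapply(seq_len(max_order), function(p) {
    ic_for_order(Y, p, max_order, criterion)
  }, numeric(1))
  if (all(is.na(ic))) abort_fit("all candidate orders failed to fit")
  which.min(ic) # first minimum -> smaller order on ties
}
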