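#' Estimate ICA model order from the eigenvalue spectrum
#'
#' Chooses the number of components by minimizing an information criterion
#' computed from the eigenvalues of the temporal covariance of the
#' (demeaned, variance-normalized) data, in the standard probabilistic-PCA
#' order-selection form: for candidate order k the log-likelihood of the
#' isotropic-residual model is
#' `L(k) = -v (t - k) log( a_k / g_k )`,
#' where `a_k` and `g_k` are the arithmetic and geometric means of the
#' discarded eigenvalues and `v` is the number of spatial samples, penalized
#' by the parameter count `m(k) = k (2t - k) + 1`:
#' AIC = -2L + 2m, BIC = -2L + m log v, MDL = -L + m/2 log v (BIC and MDL
#' share an argmin in this form). Ties are broken toward the smaller order.
#'
#' @param run an [fmri_run()].
#' @param method `"AIC"`, `"BIC"` or `"MDL"`.
#' @return The estimated order, an integer in `[1, t - 1]`.
#' @export
estimate_dim <- function(run, method = c("AIC", "BIC", "MDL")) {
  method <- match.arg(method)
  x <- run$data
  t <- nrow(x); v <- ncol(x)
  if (t < 3) stop("need at least 3 volumes")
  x <- sweep(x, 2, colMeans(x), "-")
  vals <- eigen(tcrossprod(x) / v, symmetric = TRUE, only.values = TRUE)$values
  # demeaning removes one temporal degree of freedom: drop the null direction
  te <- t - 1L
  vals <- pmax(vals[seq_len(te)], .Machine$double.eps)
  kmax <- te - 1L
  crit <- numeric(kmax)
  for (k in seq_len(kmax)) {
    rest <- vals[(k + 1):te]
    a <- mean(rest)
    g <- exp(mean(log(rest)))
    ll <- -v * (te - k) * log(a / g)      # log-likelihood (<= 0)
    m <- k * (2 * te - k) + 1
    crit[k] <- switch(method,
      AIC = -2 * ll + 2 * m,
      BIC = -2 * ll + m * log(v),
      MDL = -ll + m / 2 * log(v))
  }
  which.min(crit)   # which.min takes the first (smallest k) on ties
}
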