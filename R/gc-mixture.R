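#' Univariate Gaussian mixture fit of contig GC content
#'
#' Expectation-maximisation fit of a k-component normal mixture to contig GC
#' fractions, used to validate the host/symbiont split: a mixed holobiont
#' assembly shows two GC modes (host near 0.40, dinoflagellate symbiont near
#' 0.53) that the fitted component means should recover.
#'
#' The fit is deterministic: components are initialised at evenly spaced
#' quantiles of the data (the 25th/75th percentiles for k = 2), with equal
#' weights and the pooled standard deviation. Iteration stops when the
#' log-likelihood improves by less than `tol` or after `max_iter`
#' iterations; a floor of 1e-4 on component standard deviations guards
#' degenerate (single-valued) inputs, which are flagged.
#'
#' @param gc numeric vector of GC fractions (or a contig data frame with a
#'   `gc` column); at least `10 * k` values.
#' @param k number of components.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list with `means`, `sds`, `weights` (components sorted by
#'   ascending mean), `responsibilities` (n x k matrix), `loglik`,
#'   `converged`, `degenerate`.
#' @export
gc_mixture <- function(gc, k = 2, max_iter = 500, tol = 1e-8) {
  if (is.data.frame(gc)) gc <- gc$gc
  gc <- gc[!is.na(gc)]
  n <- length(gc)
  if (n < 10 * k) stop("need at least ", 10 * k, " GC values for k = ", k)
  sd_floor <- 1e-4

  probs <- (seq_len(k) * 2 - 1) / (2 * k)      # k=2 -> 0.25, 0.75
  mu <- as.numeric(quantile(gc, probs, names = FALSE))
  sigma <- rep(max(sd(gc), sd_floor), k)
  w <- rep(1 / k, k)

  loglik <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  dens <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) dens[, j] <- w[j] * dnorm(gc, mu[j], sigma[j])
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * gc) / nk
    for (j in seq_len(k)) {
      v <- sum(resp[, j] * (gc - mu[j])^2) / nk[j]
      s <- sqrt(max(v, 0))
      if (s < sd_floor) { s <- sd_floor; degenerate <- TRUE }
      sigma[j] <- s
    }
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      loglik <- ll; converged <- TRUE; break
    }
    loglik <- ll
  }
  ord <- order(mu)
  list(means = mu[ord], sds = sigma[ord], weights = w[ord],
       responsibilities = resp[, ord, drop = FALSE],
       loglik = loglik, converged = converged, degenerate = degenerate)
}
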