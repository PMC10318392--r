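#' Split-chain potential scale reduction factor (Rhat)
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed on the split chains, so that trends within a chain are
#' detected as well as disagreement between chains. Values near 1 indicate
#' convergence; the conventional alarm threshold is 1.05. Chains with zero
#' within-chain variance but different means return `Inf`; identical
#' constant chains return 1.
#'
#' @param x Numeric matrix of draws, iterations x chains.
#' @return Scalar Rhat.
#' @export
rhat <- function(x) {
  x <- split_chains(as.matrix(x))
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2L) stop("Rhat requires at least 2 chains")
  if (n < 2L) stop("Rhat requires at least 2 draws per split chain")
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B > 0) Inf else 1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Split-chain effective sample size using chain-averaged autocorrelations
#' combined with Geyer's initial monotone positive sequence truncation. For
#' independent draws the estimate is close to the total number of draws.
#'
#' @param x Numeric matrix of draws, iterations x chains.
#' @return Scalar effective sample size.
#' @export
ess_bulk <- function(x) {
  x <- split_chains(as.matrix(x))
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) stop("ESS requires at least 4 draws per split chain")
  vars <- apply(x, 2, var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- if (m > 1L) n * var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * W + B / n
  # chain-averaged autocovariances (biased, n denominator)
  acov <- sapply(seq_len(m), function(j)
    acf(x[, j], lag.max = n - 1L, type = "covariance",
        plot = FALSE, demean = TRUE)$acf[, 1, 1] * (n - 1) / n)
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus # rho[1] is lag 0
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  max_pairs <- (length(rho) - 1L) %/% 2L
  pair_sum <- numeric(0)
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k] + rho[2 * k + 1]
    if (p <= 0) break
    p <- min(p, prev)
    pair_sum <- c(pair_sum, p)
    prev <- p
  }
  tau <- -1 + 2 * (rho[1] + sum(pair_sum)) # rho[1] = 1 by construction
  max(n * m / max(tau, .Machine$double.eps), 1)
}

split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  if (h < 1L) stop("too few draws to split chains")
  cbind(x[seq_len(h), , drop = FALSE],
        x[seq.int(n - h + 1L, n), , drop = FALSE])
}

#' Posterior summaries and convergence diagnostics of a fit
#'
#' Per-parameter posterior mean, standard deviation, central 95% credible
#' interval, split-chain Rhat and effective sample size, with an overall
#' convergence flag (all Rhat below `rhat_max`). The derived overdispersion
#' `lambda = 1 / (1 + kappa)` is reported alongside the sampled parameters.
#'
#' @param fit A [bb_fit()] object.
#' @param rhat_max Convergence threshold on Rhat (default 1.05).
#' @return A data.frame of class `bb_diagnostics`, one row per parameter,
#'   with attribute `converged`.
#' @export
mcmc_diagnostics <- function(fit, rhat_max = 1.05) {
  stopifnot(inherits(fit, "bb_fit"))
  d <- fit$draws
  if (dim(d)[2] < 2L)
    stop("Rhat requires at least 2 chains; refit with `chains >= 2`")
  if (dim(d)[1] < 10L)
    stop("diagnostics require at least 10 kept draws per chain")
  pars <- dimnames(d)[[3]]
  lam <- 1 / (1 + d[, , 7:9, drop = FALSE])
  dimnames(lam)[[3]] <- paste0("lambda[", 1:3, "]")
  rows <- lapply(c(seq_along(pars), 10:12), function(k) {
    m <- if (k <= 9) d[, , k] else lam[, , k - 9]
    v <- as.vector(m)
    data.frame(parameter = if (k <= 9) pars[k] else dimnames(lam)[[3]][k - 9],
               mean = mean(v), sd = stats::sd(v),
               q2.5 = unname(quantile(v, 0.025)),
               q97.5 = unname(quantile(v, 0.975)),
               rhat = rhat(m), ess = ess_bulk(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # convergence judged on the sampled parameters (lambda is a monotone
  # transform of kappa and adds no information)
  attr(out, "converged") <- all(out$rhat[1:9] < rhat_max)
  attr(out, "rhat_max") <- rhat_max
  class(out) <- c("bb_diagnostics", "data.frame")
  out
}

#' @export
print.bb_diagnostics <- function(x, digits = 4, ...) {
  cat("Posterior summary (", nrow(x), " parameters)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(if (isTRUE(attr(x, "converged"))) "All Rhat below" else
      "WARNING: some Rhat at or above", attr(x, "rhat_max"), "\n")
  invisible(x)
}
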