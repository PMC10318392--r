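#' @export
print.bb_fit <- function(x, ...) {
  cat("Beta-binomial genotype mixture fit\n")
  cat(sprintf("  %d training sites; %d chains x (%d warmup + %d kept)\n",
              x$n_sites, x$config$chains, x$config$warmup, x$config$keep))
  cm <- coef(x)
  cat("  posterior means:\n")
  cat(sprintf("    theta  = (%.3f, %.3f, %.3f)\n", cm$theta[1], cm$theta[2],
              cm$theta[3]))
  cat(sprintf("    mu     = (%.4f, %.4f, %.4f)\n", cm$mu[1], cm$mu[2],
              cm$mu[3]))
  cat(sprintf("    kappa  = (%.1f, %.1f, %.1f)\n", cm$kappa[1], cm$kappa[2],
              cm$kappa[3]))
  invisible(x)
}

#' @export
#' @rdname mcmc_diagnostics
#' @param object,... Method arguments.
summary.bb_fit <- function(object, rhat_max = 1.05, ...) {
  mcmc_diagnostics(object, rhat_max = rhat_max)
}

#' Posterior-mean parameter estimates
#'
#' @param object A [bb_fit()] object.
#' @param ... Unused.
#' @return List with posterior means `theta`, `mu`, `kappa` and the derived
#'   overdispersion `lambda = 1 / (1 + kappa)`.
#' @export
coef.bb_fit <- function(object, ...) {
  m <- colMeans(flat_draws(object))
  list(theta = unname(m[1:3]), mu = unname(m[4:6]),
       kappa = unname(m[7:9]), lambda = unname(1 / (1 + m[7:9])))
}

#' Log-likelihood of the training data at the posterior mean draws
#'
#' Returns the posterior mean of the per-draw mixture log-likelihood, a
#' convenient single-number fit summary (not a maximized likelihood; no
#' degrees of freedom are attached).
#'
#' @param object A [bb_fit()] object.
#' @param ... Unused.
#' @export
logLik.bb_fit <- function(object, ...) {
  structure(mean(object$loglik), class = "logLik", df = NA_integer_,
            nobs = object$n_sites)
}

#' Trace and density plots for a fitted mixture
#'
#' One row per parameter: the trace of every chain (left) and the pooled
#' posterior histogram (right). Intended as the visual convergence
#' complement to [mcmc_diagnostics()].
#'
#' @param x A [bb_fit()] object.
#' @param pars Parameter names to plot (default: the three component means).
#' @param ... Unused.
#' @export
plot.bb_fit <- function(x, pars = paste0("mu[", 1:3, "]"), ...) {
  d <- x$draws
  all_pars <- dimnames(d)[[3]]
  bad <- setdiff(pars, all_pars)
  if (length(bad)) stop("unknown parameter: ", bad[1L])
  old <- par(mfrow = c(length(pars), 2), mar = c(2.5, 4, 1.5, 0.5))
  on.exit(par(old))
  for (p in pars) {
    k <- match(p, all_pars)
    m <- d[, , k, drop = FALSE]
    matplot_traces(m[, , 1, drop = TRUE], p)
    hist(as.vector(m), breaks = 40, main = "", xlab = p, col = "grey80",
         border = "grey40")
  }
  invisible(x)
}

matplot_traces <- function(m, label) {
  m <- as.matrix(m)
  plot(NA, xlim = c(1, nrow(m)), ylim = range(m), xlab = "iteration",
       ylab = label, main = "")
  for (j in seq_len(ncol(m)))
    lines(seq_len(nrow(m)), m[, j], col = j, lwd = 0.5)
}

#' Call genotypes with a fitted mixture
#'
#' `predict()` on a fitted mixture applies [call_genotypes()] to a new
#' allele-count table — the learned parameters are deliberately decoupled
#' from the sample they were learned on, so the same fit can call genotypes
#' in any sample from the same process (fit once, call many).
#'
#' @param object A [bb_fit()] object.
#' @param newdata Allele-count table to call.
#' @param ... Passed to [call_genotypes()] (`threshold`, `prior_mode`,
#'   `eaf`, `method`, `ndraws`).
#' @return A `genotype_calls` data frame.
#' @export
predict.bb_fit <- function(object, newdata, ...) {
  call_genotypes(object, newdata, ...)
}

#' Simulate allele counts from a fitted mixture
#'
#' Draws synthetic datasets from the generative process at the posterior
#' mean parameters — a quick posterior-predictive check against the
#' training data.
#'
#' @param object A [bb_fit()] object.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param n_sites Sites per dataset.
#' @param ... Passed to [simulate_counts()] (depth model arguments).
#' @return A list of `sim_truth` objects of length `nsim`.
#' @export
simulate.bb_fit <- function(object, nsim = 1, seed = 1L, n_sites = 1000L,
                            ...) {
  cm <- coef(object)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, nsim)
  lapply(seq_len(nsim), function(i)
    simulate_counts(n_sites, theta = cm$theta / sum(cm$theta), mu = cm$mu,
                    kappa = cm$kappa, seed = seeds[i], ...))
}
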