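# Independent oracles, written from the defining formulas in plain
# arithmetic. They deliberately avoid the package's own code paths.

# Beta-binomial pmf by direct evaluation of choose(n, x) * B(x + a, n - x +
# b) / B(a, b); safe for the small n used in oracle comparisons.
oracle_bb_pmf <- function(x, n, mu, kappa) {
  a <- mu * kappa
  b <- (1 - mu) * kappa
  if (n == 0) return(1)
  choose(n, x) * beta(x + a, n - x + b) / beta(a, b)
}

# Mixture log-likelihood by per-site three-term summation in plain
# (non-log) arithmetic.
oracle_mix_ll <- function(counts, theta, mu, kappa) {
  per_site <- vapply(seq_len(nrow(counts)), function(l) {
    s <- 0
    for (g in 1:3)
      s <- s + theta[g] * oracle_bb_pmf(counts$n_alt[l], counts$n_total[l],
                                        mu[g], kappa[g])
    log(s)
  }, numeric(1))
  sum(per_site)
}

# Split-chain Rhat from the defining between/within variance formula,
# written with explicit loops.
oracle_split_rhat <- function(x) {
  n <- nrow(x) %/% 2L
  halves <- list()
  for (j in seq_len(ncol(x))) {
    halves[[length(halves) + 1L]] <- x[1:n, j]
    halves[[length(halves) + 1L]] <- x[(nrow(x) - n + 1L):nrow(x), j]
  }
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- sum(vars) / m
  B <- n / (m - 1) * sum((means - mean(means))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# A degenerate fitted-model object whose every draw equals the given
# parameters; lets calling be checked against hand-evaluated Bayes rule.
point_mass_fit <- function(theta, mu, kappa, keep = 4L, chains = 2L) {
  par_names <- c(paste0("theta[", 1:3, "]"), paste0("mu[", 1:3, "]"),
                 paste0("kappa[", 1:3, "]"))
  draws <- array(rep(c(theta, mu, kappa), each = keep * chains),
                 dim = c(keep, chains, 9L),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 par_names))
  structure(list(draws = draws, loglik = matrix(0, keep, chains),
                 accept = NULL, priors = bb_priors(), n_sites = 0L,
                 config = list(chains = chains, warmup = 0L, keep = keep,
                               seed = 1L)),
            class = "bb_fit")
}

# Shorthand: a bare counts table without genomic coordinates.
counts_tab <- function(n_alt, n_total) {
  data.frame(site_id = sprintf("s%d", seq_along(n_alt)),
             n_alt = as.integer(n_alt), n_total = as.integer(n_total),
             stringsAsFactors = FALSE)
}

# Reduced-budget fit for unit tests that only need a usable posterior.
quick_fit <- function(counts, seed = 1L, chains = 2L, warmup = 300L,
                      keep = 300L, ...) {
  bb_fit(counts, chains = chains, warmup = warmup, keep = keep,
         seed = seed, ...)
}
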