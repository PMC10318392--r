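#' Select a random training subset of SNPs
#'
#' Training sites are drawn uniformly at random, without replacement, from
#' the sites passing a minimum-depth filter (default: at least 10 supporting
#' reads). A modest subset (default 1000 SNPs) is enough to learn the
#' mixture parameters; using every site would only slow the MCMC down. If
#' fewer eligible sites exist than requested, all of them are returned and
#' the shortfall recorded in the `"shortfall"` attribute.
#'
#' @param counts Allele-count table (see [allele_counts()]).
#' @param size Requested number of training SNPs.
#' @param min_depth Minimum `n_total` for eligibility (inclusive).
#' @param seed Integer seed; selection is reproducible given it.
#' @return The selected rows of `counts`, with attributes `requested`,
#'   `shortfall`, `min_depth` and `seed`.
#' @export
select_training <- function(counts, size = 1000L, min_depth = 10L,
                            seed = 1L) {
  counts <- validate_counts(counts)
  if (nrow(counts) == 0L) stop("`counts` must contain at least one site")
  eligible <- counts[counts$n_total >= min_depth, , drop = FALSE]
  if (nrow(eligible) == 0L)
    stop("no sites pass the training depth filter (n_total >= ",
         min_depth, ")")
  set.seed(seed)
  take <- min(size, nrow(eligible))
  out <- eligible[sort(sample.int(nrow(eligible), take)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "requested") <- as.integer(size)
  attr(out, "shortfall") <- as.integer(size - take)
  attr(out, "min_depth") <- as.integer(min_depth)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Fit the beta-binomial genotype mixture by MCMC
#'
#' Learns the mixture proportions `theta`, component means `mu` and
#' concentrations `kappa` of the three genotype components from a training
#' table of allele counts. The latent genotype labels are marginalized
#' analytically inside the likelihood, and the posterior is sampled with an
#' adaptive Metropolis-within-Gibbs random walk on transformed coordinates
#' (stick-breaking logits for `theta`, logit `mu`, log `kappa`); step sizes
#' adapt toward a 44% acceptance rate during warmup and are frozen
#' afterwards. Label switching is resolved by the ascending-`mu` constraint:
#' component 1 is homozygous reference, 2 heterozygous, 3 homozygous
#' alternative.
#'
#' The default budget keeps 1000 draws per chain from 4 chains after 1000
#' warmup iterations each, 4000 posterior draws in total. Chains are run
#' sequentially from one RNG stream seeded with `seed`, so a fit is bitwise
#' reproducible.
#'
#' @param counts Training allele-count table, e.g. from
#'   [select_training()].
#' @param priors A [bb_priors()] object.
#' @param chains Number of chains (>= 2 so that convergence diagnostics are
#'   defined).
#' @param warmup,keep Warmup iterations discarded and draws kept per chain.
#' @param seed Integer seed.
#' @param .allow_empty Internal: permit an empty count table, in which case
#'   the chains sample the (ordered-mean) prior. Used to validate the
#'   sampler against analytic prior moments.
#' @return An object of class `bb_fit` with elements `draws` (array
#'   `keep x chains x 9`, parameters `theta[1..3]`, `mu[1..3]`,
#'   `kappa[1..3]`), `loglik`, `accept`, `priors`, `config`, `n_sites`.
#'   Methods: `print`, `summary`, `coef`, `plot`, `predict`, `simulate`,
#'   `logLik`.
#' @examples
#' sim <- simulate_counts(300, theta = c(0.6, 0.25, 0.15), seed = 7)
#' fit <- bb_fit(sim$counts, chains = 2, warmup = 150, keep = 150, seed = 7)
#' coef(fit)
#' @export
bb_fit <- function(counts, priors = bb_priors(), chains = 4L,
                   warmup = 1000L, keep = 1000L, seed = 1L,
                   .allow_empty = FALSE) {
  if (chains < 1L) stop("`chains` must be at least 1")
  if (chains < 2L && !.allow_empty)
    message("note: convergence diagnostics (Rhat) require >= 2 chains")
  if (warmup < 0L || keep < 1L)
    stop("`warmup` must be >= 0 and `keep` >= 1")
  if (nrow(counts) == 0L && !.allow_empty)
    stop("`counts` must contain at least one training site")
  counts <- validate_counts(counts)

  if (nrow(counts) > 0L) {
    d <- dedupe_counts(counts$n_alt, counts$n_total)
  } else {
    d <- list(x = integer(0), n = integer(0), w = numeric(0))
  }

  set.seed(seed)
  par_names <- c(paste0("theta[", 1:3, "]"), paste0("mu[", 1:3, "]"),
                 paste0("kappa[", 1:3, "]"))
  draws <- array(NA_real_, dim = c(keep, chains, 9L),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 par_names))
  loglik <- matrix(NA_real_, keep, chains)
  accept <- matrix(NA_real_, 8L, chains)

  for (ch in seq_len(chains)) {
    z0 <- init_state(priors)
    res <- .bb_mcmc_cpp(d$x, d$n, d$w, priors$dirichlet, priors$alpha,
                           priors$beta, as.integer(warmup),
                           as.integer(keep), z0,
                           rep(0.5, 8L))
    if (any(!is.finite(res$draws)))
      stop("sampler produced non-finite draws in chain ", ch)
    draws[, ch, ] <- res$draws
    loglik[, ch] <- res$loglik
    accept[, ch] <- res$accept
  }

  structure(list(
    draws = draws, loglik = loglik, accept = accept, priors = priors,
    n_sites = nrow(counts),
    config = list(chains = as.integer(chains), warmup = as.integer(warmup),
                  keep = as.integer(keep), seed = as.integer(seed),
                  shortfall = attr(counts, "shortfall"),
                  min_depth = attr(counts, "min_depth"))),
    class = "bb_fit")
}

# Draw an initial unconstrained state from the priors (ordered mu).
init_state <- function(priors) {
  mu <- sort(rbeta(3, priors$alpha, priors$beta))
  while (any(diff(mu) <= 0)) mu <- sort(rbeta(3, priors$alpha, priors$beta))
  kappa <- rgamma(3, shape = priors$alpha + priors$beta, rate = 1)
  th <- rgamma(3, shape = priors$dirichlet, rate = 1)
  th <- th / sum(th)
  v1 <- th[1]
  v2 <- th[2] / (1 - th[1])
  c(stats::qlogis(v1), stats::qlogis(v2), stats::qlogis(mu), log(kappa))
}

# Flatten the draw array to an (S x 9) matrix across chains.
flat_draws <- function(fit) {
  d <- fit$draws
  m <- matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2], ncol = 9)
  colnames(m) <- dimnames(d)[[3]]
  m
}
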