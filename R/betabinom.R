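#' Beta-binomial probability mass function (mean/concentration form)
#'
#' Density of the beta-binomial distribution parameterized by its mean
#' alt-allele fraction `mu` and concentration `kappa = alpha + beta`, the
#' form in which the genotype components of the mixture are expressed:
#' `alpha = mu * kappa`, `beta = (1 - mu) * kappa`. Computed entirely in log
#' space via log-gamma functions, so depths up to millions of reads do not
#' overflow. A site with `size = 0` carries no information and has
#' probability 1 (`log` density 0).
#'
#' @param x Integer vector, number of reads supporting the alternative
#'   allele. Must satisfy `0 <= x <= size`.
#' @param size Integer vector, total reads overlapping the site.
#' @param mu Mean fraction in (0, 1). Recycled against `x`.
#' @param kappa Concentration (> 0); large values approach the binomial.
#' @param log Return log density?
#' @return Numeric vector of (log) probabilities.
#' @examples
#' dbetabinom(3, 10, mu = 0.5, kappa = 4)
#' sum(dbetabinom(0:10, 10, 0.5, 2)) # 1
#' @export
dbetabinom <- function(x, size, mu, kappa, log = FALSE) {
  k <- max(length(x), length(size), length(mu), length(kappa))
  x <- rep_len(as.integer(x), k)
  size <- rep_len(as.integer(size), k)
  mu <- rep_len(as.numeric(mu), k)
  kappa <- rep_len(as.numeric(kappa), k)
  if (any(is.na(x)) || any(is.na(size)))
    stop("`x` and `size` must be non-missing integers")
  if (any(x < 0L) || any(size < 0L))
    stop("`x` and `size` must be non-negative")
  if (any(x > size))
    stop("`x` exceeds `size` at position ", which(x > size)[1L])
  if (any(mu <= 0 | mu >= 1))
    stop("`mu` must lie strictly in (0, 1)")
  if (any(kappa <= 0))
    stop("`kappa` must be positive")
  lp <- .bb_logpmf_cpp(x, size, mu, kappa)
  if (log) lp else exp(lp)
}

#' Sample from the beta-binomial (mean/concentration form)
#'
#' Draws via the compound construction `p ~ Beta(mu*kappa, (1-mu)*kappa)`,
#' `x ~ Binomial(size, p)`. The degenerate boundaries `mu = 0` and `mu = 1`
#' are allowed here (all-reference / all-alternative reads), which is
#' convenient for noise-free simulation limits.
#'
#' @param n Number of draws.
#' @param size Total reads (recycled).
#' @param mu Mean fraction in \[0, 1\] (recycled).
#' @param kappa Concentration (> 0, may be `Inf` for the exact binomial).
#' @return Integer vector of alternative-allele read counts.
#' @export
rbetabinom <- function(n, size, mu, kappa) {
  size <- rep_len(as.integer(size), n)
  mu <- rep_len(as.numeric(mu), n)
  kappa <- rep_len(as.numeric(kappa), n)
  if (any(mu < 0 | mu > 1)) stop("`mu` must lie in [0, 1]")
  if (any(kappa <= 0)) stop("`kappa` must be positive")
  p <- numeric(n)
  inner <- mu > 0 & mu < 1 & is.finite(kappa)
  p[inner] <- rbeta(sum(inner), mu[inner] * kappa[inner],
                    (1 - mu[inner]) * kappa[inner])
  p[!inner] <- mu[!inner] # boundary or binomial limit
  rbinom(n, size, p)
}

#' Convert beta shape parameters to mean and overdispersion
#'
#' Maps `(alpha, beta)` to the mean `mu = alpha / (alpha + beta)` and the
#' overdispersion `lambda = 1 / (1 + alpha + beta)`, both in (0, 1).
#' `lambda` is the intraclass correlation of the beta-binomial; `lambda -> 0`
#' recovers the binomial. The concentration is `kappa = alpha + beta =
#' (1 - lambda) / lambda`.
#'
#' @param alpha,beta Positive shape parameters.
#' @return List with components `mu`, `lambda` and `kappa`.
#' @seealso [mulambda_to_ab()] for the inverse.
#' @export
ab_to_mulambda <- function(alpha, beta) {
  if (any(alpha <= 0)) stop("`alpha` must be positive")
  if (any(beta <= 0)) stop("`beta` must be positive")
  list(mu = alpha / (alpha + beta), lambda = 1 / (1 + alpha + beta),
       kappa = alpha + beta)
}

#' Convert mean and overdispersion to beta shape parameters
#'
#' @param mu Mean in (0, 1).
#' @param lambda Overdispersion in (0, 1).
#' @return List with components `alpha` and `beta`.
#' @seealso [ab_to_mulambda()]
#' @export
mulambda_to_ab <- function(mu, lambda) {
  if (any(mu <= 0 | mu >= 1)) stop("`mu` must lie strictly in (0, 1)")
  if (any(lambda <= 0 | lambda >= 1))
    stop("`lambda` must lie strictly in (0, 1)")
  kappa <- (1 - lambda) / lambda
  list(alpha = mu * kappa, beta = (1 - mu) * kappa)
}

#' Prior specification for the genotype mixture
#'
#' Hyperparameters of the default priors: `theta ~ Dirichlet(1, 1, 1)`,
#' `mu_g ~ Beta(alpha[g], beta[g])` and `kappa_g ~ Gamma(alpha[g] + beta[g],
#' rate 1)`. The default Beta hyperparameters `(1, 499)`, `(10, 10)`,
#' `(499, 1)` centre the component means near 0.002, 0.5 and 0.998 — almost
#' pure reference reads for homozygous reference, balanced alleles for
#' heterozygotes, almost pure alternative reads for homozygous alternative —
#' while leaving the heterozygote mean diffuse enough to absorb reference
#' mapping bias.
#'
#' @param dirichlet Length-3 positive vector, Dirichlet concentration for the
#'   mixture weights.
#' @param alpha,beta Length-3 positive vectors, Beta hyperparameters per
#'   genotype component (in ascending-mean order: hom-ref, het, hom-alt).
#' @return An object of class `bb_priors`.
#' @export
bb_priors <- function(dirichlet = c(1, 1, 1),
                      alpha = c(1, 10, 499),
                      beta = c(499, 10, 1)) {
  stopifnot(length(dirichlet) == 3L, length(alpha) == 3L, length(beta) == 3L)
  if (any(dirichlet <= 0) || any(alpha <= 0) || any(beta <= 0))
    stop("all prior hyperparameters must be positive")
  structure(list(dirichlet = as.numeric(dirichlet),
                 alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "bb_priors")
}

#' @export
print.bb_priors <- function(x, ...) {
  cat("Genotype mixture priors\n")
  cat("  theta   ~ Dirichlet(", paste(x$dirichlet, collapse = ", "), ")\n")
  for (g in 1:3)
    cat(sprintf("  mu[%d]   ~ Beta(%g, %g);  kappa[%d] ~ Gamma(%g, 1)\n",
                g, x$alpha[g], x$beta[g], g, x$alpha[g] + x$beta[g]))
  invisible(x)
}

#' Joint log prior density of the mixture parameters
#'
#' Sum of the log densities of the mixture weights (Dirichlet), each
#' component mean (Beta) and each concentration (Gamma with rate 1), on the
#' natural (constrained) scale. Parameter values on the boundary of support
#' return `-Inf`.
#'
#' @param theta Length-3 simplex of mixture weights.
#' @param mu Length-3 vector of component means in (0, 1).
#' @param kappa Length-3 vector of positive concentrations.
#' @param priors A [bb_priors()] object.
#' @return Scalar log density.
#' @export
bb_log_prior <- function(theta, mu, kappa, priors = bb_priors()) {
  stopifnot(length(theta) == 3L, length(mu) == 3L, length(kappa) == 3L)
  if (abs(sum(theta) - 1) > 1e-8) stop("`theta` must sum to 1")
  if (any(theta <= 0) || any(theta >= 1) ||
      any(mu <= 0) || any(mu >= 1) || any(kappa <= 0))
    return(-Inf)
  c0 <- priors$dirichlet
  ld <- lgamma(sum(c0)) - sum(lgamma(c0)) + sum((c0 - 1) * log(theta))
  lb <- sum(dbeta(mu, priors$alpha, priors$beta, log = TRUE))
  lg <- sum(dgamma(kappa, shape = priors$alpha + priors$beta, rate = 1,
                   log = TRUE))
  ld + lb + lg
}

#' Mixture log-likelihood of allele counts
#'
#' Log-likelihood of a table of per-site allele counts under the three-
#' component beta-binomial mixture: for each site the three component
#' likelihoods are weighted by the mixture proportions and summed
#' (log-sum-exp in log space), then summed over sites. Sites with zero depth
#' contribute exactly 0.
#'
#' @param counts Data frame with integer columns `n_alt` and `n_total`
#'   (see [allele_counts()]).
#' @param theta Length-3 simplex of genotype proportions.
#' @param mu,kappa Length-3 component means and concentrations.
#' @return Scalar log-likelihood.
#' @export
bb_mixture_loglik <- function(counts, theta, mu, kappa) {
  counts <- validate_counts(counts)
  if (nrow(counts) == 0L) stop("`counts` must contain at least one site")
  stopifnot(length(theta) == 3L, length(mu) == 3L, length(kappa) == 3L)
  if (abs(sum(theta) - 1) > 1e-8) stop("`theta` must sum to 1")
  if (any(theta < 0)) stop("`theta` must be non-negative")
  if (any(mu <= 0 | mu >= 1)) stop("`mu` must lie strictly in (0, 1)")
  if (any(kappa <= 0)) stop("`kappa` must be positive")
  d <- dedupe_counts(counts$n_alt, counts$n_total)
  logcomp <- vapply(1:3, function(g)
    .bb_logpmf_cpp(d$x, d$n, mu[g], kappa[g]), numeric(length(d$x)))
  logcomp <- matrix(logcomp, ncol = 3L)
  # log(0) weights are legal: drop those components from the sum
  ltheta <- ifelse(theta > 0, log(theta), -Inf)
  .mix_loglik_cpp(logcomp, ltheta, d$w)
}

# Collapse repeated (n_alt, n_total) pairs into unique rows with weights;
# the component log pmf depends on a site only through this pair.
dedupe_counts <- function(x, n) {
  key <- x * (max(n) + 1) + n
  tab <- tapply(rep(1L, length(key)), key, sum)
  ukey <- as.numeric(names(tab))
  list(x = as.integer(ukey %/% (max(n) + 1)),
       n = as.integer(ukey %% (max(n) + 1)),
       w = as.numeric(tab))
}
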