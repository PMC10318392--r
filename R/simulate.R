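#' Simulate allele counts with known genotypes
#'
#' Generates a synthetic cohort sample under the generative process the
#' mixture model assumes: per site a genotype `g ~ Categorical(theta)` (or
#' Hardy-Weinberg frequencies derived from an allele frequency `eaf`), a
#' total depth from the chosen depth model, and an alternative-allele count
#' `n_alt ~ BetaBinomial(n_total, mu[g+1], kappa[g+1])`. Depth models:
#' `"poisson"` (default, mean 30 — typical exonic RNA-seq coverage),
#' `"nbinom"` (adds the between-gene coverage dispersion characteristic of
#' RNA-seq), `"fixed"`. A lower depth truncation can be imposed with
#' `min_depth` (rejection sampling).
#'
#' @param n_sites Number of SNPs to simulate.
#' @param theta Length-3 genotype proportions (exclusive with `eaf`).
#' @param eaf Alternative-allele frequency in (0, 1); genotype proportions
#'   are then the Hardy-Weinberg `((1-f)^2, 2f(1-f), f^2)`.
#' @param mu Length-3 ascending component means. The default heterozygote
#'   mean 0.48 mimics mild reference mapping bias.
#' @param kappa Length-3 concentrations; the default `(500, 20, 500)` makes
#'   homozygote counts nearly binomial while the heterozygote is strongly
#'   overdispersed, as allele-specific expression produces.
#' @param depth Depth model, one of `"poisson"`, `"fixed"`, `"nbinom"`.
#' @param depth_mean Mean depth (Poisson/negative-binomial) or the fixed
#'   depth.
#' @param depth_size Negative-binomial size (dispersion) parameter.
#' @param min_depth Lower truncation for simulated depths (0 = none).
#' @param seed Integer seed; the run is bitwise reproducible given it.
#' @param chrom Chromosome label used for the synthetic site ids.
#' @return An object of class `sim_truth`: list with `counts` (an allele-
#'   count table), `genotypes` (integer vector in 0/1/2), and `config`.
#' @examples
#' sim <- simulate_counts(200, theta = c(0.6, 0.25, 0.15), seed = 1)
#' table(sim$genotypes)
#' @export
simulate_counts <- function(n_sites, theta = NULL, eaf = NULL,
                            mu = c(0.002, 0.48, 0.998),
                            kappa = c(500, 20, 500),
                            depth = c("poisson", "fixed", "nbinom"),
                            depth_mean = 30, depth_size = 5,
                            min_depth = 0, seed = 1L, chrom = "chrS") {
  depth <- match.arg(depth)
  if (is.null(theta) == is.null(eaf))
    stop("specify exactly one of `theta` or `eaf`")
  if (!is.null(eaf)) {
    if (eaf <= 0 || eaf >= 1) stop("`eaf` must lie strictly in (0, 1)")
    theta <- c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2)
  }
  if (length(theta) != 3L || any(theta < 0) || abs(sum(theta) - 1) > 1e-8)
    stop("`theta` must be a length-3 simplex")
  if (length(mu) != 3L || is.unsorted(mu, strictly = TRUE))
    stop("`mu` must be ascending across the three genotypes")
  if (any(kappa <= 0)) stop("`kappa` must be positive")
  if (n_sites < 1L) stop("`n_sites` must be at least 1")

  config <- list(n_sites = n_sites, theta = theta, eaf = eaf, mu = mu,
                 kappa = kappa, depth = depth, depth_mean = depth_mean,
                 depth_size = depth_size, min_depth = min_depth,
                 seed = seed, chrom = chrom)
  set.seed(seed)
  g <- sample.int(3L, n_sites, replace = TRUE, prob = theta) - 1L
  n_total <- switch(depth,
    fixed   = rep(as.integer(depth_mean), n_sites),
    poisson = rpois(n_sites, depth_mean),
    nbinom  = rnbinom(n_sites, mu = depth_mean, size = depth_size))
  if (min_depth > 0) {
    low <- which(n_total < min_depth)
    while (length(low)) { # truncated depth by rejection
      n_total[low] <- switch(depth,
        fixed   = rep(as.integer(depth_mean), length(low)),
        poisson = rpois(length(low), depth_mean),
        nbinom  = rnbinom(length(low), mu = depth_mean, size = depth_size))
      low <- low[n_total[low] < min_depth]
    }
  }
  n_alt <- rbetabinom(n_sites, n_total, mu[g + 1L], kappa[g + 1L])
  counts <- allele_counts(chrom = chrom, pos = seq_len(n_sites),
                          ref = "A", alt = "G",
                          n_alt = n_alt, n_total = n_total)
  structure(list(counts = counts, genotypes = g, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated allele counts:", nrow(x$counts), "sites\n")
  cat("  genotype counts:",
      paste(sprintf("g=%d: %d", 0:2, tabulate(x$genotypes + 1L, 3L)),
            collapse = ", "), "\n")
  cat("  depth model:", x$config$depth, "(mean", x$config$depth_mean, ")\n")
  invisible(x)
}

#' Simulate a cohort of samples from one generative process
#'
#' Draws `n_samples` independent samples. With `shared_params = TRUE` (the
#' default) every sample uses identical mixture parameters — the setting in
#' which model parameters learned from one sample, or a pool, are
#' exchangeable across samples. With `shared_params = FALSE` each sample's
#' `mu` and `kappa` are jittered (logit/log-normal, sd 0.1) to emulate
#' between-sample variation. Per-sample seeds are derived deterministically
#' from `seed`.
#'
#' @param n_samples Number of samples (>= 1).
#' @param ... Arguments passed to [simulate_counts()].
#' @param shared_params All samples share identical parameters?
#' @param seed Master seed.
#' @return List of `sim_truth` objects, one per sample.
#' @export
simulate_cohort <- function(n_samples, ..., shared_params = TRUE,
                            seed = 1L) {
  if (n_samples < 1L) stop("`n_samples` must be at least 1")
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max %/% 2L, n_samples)
  args <- list(...)
  lapply(seq_len(n_samples), function(i) {
    a <- args
    a$seed <- sample_seeds[i]
    if (!shared_params) {
      set.seed(sample_seeds[i] + 1L)
      mu <- if (is.null(a$mu)) c(0.002, 0.48, 0.998) else a$mu
      kappa <- if (is.null(a$kappa)) c(500, 20, 500) else a$kappa
      mu <- sort(stats::plogis(stats::qlogis(mu) + rnorm(3, 0, 0.1)))
      a$mu <- mu
      a$kappa <- kappa * exp(rnorm(3, 0, 0.1))
    }
    do.call(simulate_counts, a)
  })
}
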