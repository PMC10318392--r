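#' Per-site genotype posterior probabilities
#'
#' For each site, the posterior probability of each genotype g is
#' proportional to `pi_g` times the component likelihood averaged over the
#' posterior draws of `(mu_g, kappa_g)` — a Monte-Carlo integral that
#' propagates parameter uncertainty into the calls (`method = "average"`,
#' the default). A faster plug-in mode evaluates the component likelihood at
#' the posterior means instead. The genotype prior weights `pi` are the
#' posterior-mean mixture proportions (`prior_mode = "theta"`) or per-site
#' Hardy-Weinberg probabilities computed from an effect allele frequency
#' (`prior_mode = "hwe"`, requires `eaf`). A zero-depth site returns `pi`
#' unchanged.
#'
#' @param fit A [bb_fit()] object.
#' @param counts Allele-count table of the sites to call.
#' @param prior_mode `"theta"` (learned mixture weights, default) or
#'   `"hwe"`.
#' @param eaf Numeric vector of alternative-allele frequencies (recycled),
#'   required for `prior_mode = "hwe"`; taken from `counts$eaf` when
#'   present.
#' @param method `"average"` (Monte-Carlo over draws) or `"plugin"`
#'   (posterior means).
#' @param ndraws Optionally thin to this many evenly spaced draws for the
#'   Monte-Carlo average.
#' @return Matrix `nrow(counts) x 3` of genotype probabilities, rows summing
#'   to 1.
#' @export
genotype_posteriors <- function(fit, counts,
                                prior_mode = c("theta", "hwe"), eaf = NULL,
                                method = c("average", "plugin"),
                                ndraws = NULL) {
  stopifnot(inherits(fit, "bb_fit"))
  prior_mode <- match.arg(prior_mode)
  method <- match.arg(method)
  counts <- validate_counts(counts)
  L <- nrow(counts)
  if (L == 0L)
    return(matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, paste0("g", 0:2))))

  fd <- flat_draws(fit)
  if (method == "plugin") {
    mu_d <- matrix(colMeans(fd[, 4:6, drop = FALSE]), 1L)
    kap_d <- matrix(colMeans(fd[, 7:9, drop = FALSE]), 1L)
  } else {
    idx <- seq_len(nrow(fd))
    if (!is.null(ndraws) && ndraws < nrow(fd))
      idx <- unique(round(seq(1, nrow(fd), length.out = ndraws)))
    mu_d <- fd[idx, 4:6, drop = FALSE]
    kap_d <- fd[idx, 7:9, drop = FALSE]
  }

  if (prior_mode == "theta") {
    pi_mat <- matrix(colMeans(fd[, 1:3, drop = FALSE]), L, 3L, byrow = TRUE)
  } else {
    if (is.null(eaf)) eaf <- counts$eaf
    if (is.null(eaf))
      stop("prior_mode = \"hwe\" requires `eaf` (argument or counts column)")
    f <- rep_len(as.numeric(eaf), L)
    if (any(is.na(f)) || any(f < 0 | f > 1))
      stop("`eaf` must lie in [0, 1] with no missing values")
    pi_mat <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  }

  # component likelihood averaged over draws, deduplicated by (n_alt, n_total)
  d <- dedupe_counts(counts$n_alt, counts$n_total)
  lml_u <- .post_logmeanlik_cpp(d$x, d$n, mu_d, kap_d)
  key_u <- paste(d$x, d$n)
  lml <- lml_u[match(paste(counts$n_alt, counts$n_total), key_u), ,
               drop = FALSE]

  lp <- log(pi_mat) + lml
  m <- apply(lp, 1L, max)
  p <- exp(lp - m)
  p <- p / rowSums(p)
  dimnames(p) <- list(counts$site_id, paste0("g", 0:2))
  p
}

#' Threshold genotype posteriors into hard calls
#'
#' The most probable genotype is reported when its posterior probability
#' reaches the threshold (inclusive boundary), otherwise the call is
#' missing (`NA`). The default threshold 0.99 favours accuracy over the
#' number of calls. Ties in the argmax break toward the smaller genotype
#' index.
#'
#' @param probs Length-3 probability vector or an `n x 3` matrix.
#' @param threshold Calling threshold in (1/3, 1]; at 1/3 or below the
#'   argmax would always be reported and missingness would never occur.
#' @return Integer vector of genotypes in \{0, 1, 2\} with `NA` for missing.
#' @export
hard_call <- function(probs, threshold = 0.99) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (ncol(probs) != 3L) stop("`probs` must have 3 columns")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("each row of `probs` must sum to 1")
  if (threshold <= 1 / 3 || threshold > 1)
    stop("`threshold` must lie in (1/3, 1]")
  g <- max.col(probs, ties.method = "first") - 1L
  pmax_ <- probs[cbind(seq_len(nrow(probs)), g + 1L)]
  g[pmax_ < threshold] <- NA_integer_
  g
}

#' Call genotypes for a sample
#'
#' Runs [genotype_posteriors()] over a full allele-count table and returns
#' one row per site with the genotype posterior, the dosage (expected
#' genotype `P(g=1) + 2 P(g=2)`), the thresholded hard call and the depth.
#' The dosage is always populated, including at sites whose hard call is
#' missing. Sites are returned in input order and are called independently.
#'
#' @inheritParams genotype_posteriors
#' @param threshold Hard-call probability threshold (default 0.99).
#' @return A `data.frame` of class `genotype_calls` with columns `site_id`,
#'   `n_alt`, `n_total`, `p_g0`, `p_g1`, `p_g2`, `dosage`, `hard_call`.
#' @examples
#' sim <- simulate_counts(300, theta = c(0.6, 0.25, 0.15), seed = 7)
#' fit <- bb_fit(sim$counts, chains = 2, warmup = 150, keep = 150, seed = 7)
#' calls <- call_genotypes(fit, sim$counts)
#' table(calls$hard_call, useNA = "ifany")
#' @export
call_genotypes <- function(fit, counts, threshold = 0.99,
                           prior_mode = c("theta", "hwe"), eaf = NULL,
                           method = c("average", "plugin"), ndraws = NULL) {
  counts <- validate_counts(counts)
  p <- genotype_posteriors(fit, counts, prior_mode = prior_mode, eaf = eaf,
                           method = method, ndraws = ndraws)
  out <- data.frame(site_id = counts$site_id,
                    n_alt = counts$n_alt, n_total = counts$n_total,
                    p_g0 = unname(p[, 1]), p_g1 = unname(p[, 2]),
                    p_g2 = unname(p[, 3]),
                    dosage = unname(p[, 2] + 2 * p[, 3]),
                    hard_call = if (nrow(counts)) hard_call(p, threshold)
                                else integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat("Genotype calls:", nrow(x), "sites; hard-call threshold",
      attr(x, "threshold"), "\n")
  nm <- sum(is.na(x$hard_call))
  cat("  called:", nrow(x) - nm, " missing:", nm, "\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6), digits = 4,
                                row.names = FALSE)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
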