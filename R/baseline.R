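#' Naive count-threshold genotype caller
#'
#' The baseline the mixture model is compared against: with `r = n_alt /
#' n_total`, call homozygous reference when `r < t`, homozygous alternative
#' when `r > 1 - t`, heterozygous when `t <= r <= 1 - t` (band boundaries
#' belong to the heterozygote), missing when the site has no reads. The
#' default `t = 0.1` is a common choice; tighter bands call fewer
#' heterozygotes.
#'
#' @param counts Allele-count table.
#' @param t Band half-width in (0, 0.5).
#' @return Integer vector of genotypes in \{0, 1, 2\} with `NA` at
#'   zero-depth sites.
#' @export
count_threshold_call <- function(counts, t = 0.1) {
  counts <- validate_counts(counts)
  if (t <= 0 || t >= 0.5)
    stop("`t` must lie strictly in (0, 0.5)")
  r <- counts$n_alt / counts$n_total
  g <- rep(NA_integer_, nrow(counts))
  ok <- counts$n_total > 0L
  g[ok & r < t] <- 0L
  g[ok & r > 1 - t] <- 2L
  g[ok & r >= t & r <= 1 - t] <- 1L
  g
}

#' Genotype concordance against a gold standard, stratified by genotype
#'
#' Compares hard calls with gold-standard genotypes over the sites present
#' in the truth set with at least `min_depth` supporting reads. Missing
#' calls are tallied but excluded from the accuracy denominator; strata are
#' keyed by the truth genotype. The het->hom count is the number of
#' truth-heterozygous sites called homozygous (either kind), and hom->het
#' the reverse.
#'
#' @param calls A `genotype_calls` data frame, or any data frame with
#'   columns `site_id`, `hard_call` and `n_total`.
#' @param truth Named integer vector (`site_id -> genotype` in 0/1/2) as
#'   returned by [read_truth()], or a data frame with columns `site_id` and
#'   `genotype`.
#' @param min_depth Minimum depth for a site to enter the comparison
#'   (default 10).
#' @return An object of class `concordance`: list with `by_genotype` (per-
#'   stratum concordant/discordant/missing counts and accuracy),
#'   `accuracy` (aggregate), `n_compared`, `het_to_hom`, `hom_to_het`.
#' @export
concordance_by_genotype <- function(calls, truth, min_depth = 10L) {
  truth <- as_truth_vector(truth)
  if (length(truth) == 0L) stop("`truth` must be non-empty")
  if (!all(c("site_id", "hard_call", "n_total") %in% names(calls)))
    stop("`calls` needs columns site_id, hard_call, n_total")
  if (anyDuplicated(calls$site_id))
    stop("duplicated site_id in `calls`: comparison would be ambiguous")

  keep <- calls$site_id %in% names(truth) & calls$n_total >= min_depth
  cc <- calls[keep, , drop = FALSE]
  tg <- unname(truth[cc$site_id])

  strata <- lapply(0:2, function(g) {
    sel <- tg == g
    called <- cc$hard_call[sel]
    n_missing <- sum(is.na(called))
    conc <- sum(called == g, na.rm = TRUE)
    disc <- sum(called != g, na.rm = TRUE)
    data.frame(truth_genotype = g, concordant = conc, discordant = disc,
               missing = n_missing,
               accuracy = if (conc + disc > 0) conc / (conc + disc)
                          else NA_real_)
  })
  by_genotype <- do.call(rbind, strata)
  called <- !is.na(cc$hard_call)
  conc_all <- sum(cc$hard_call[called] == tg[called])
  n_comp <- sum(called)
  het_to_hom <- sum(tg == 1L & called & cc$hard_call != 1L)
  hom_to_het <- sum(tg != 1L & called & cc$hard_call == 1L)
  structure(list(by_genotype = by_genotype,
                 accuracy = if (n_comp > 0) conc_all / n_comp else NA_real_,
                 n_compared = n_comp,
                 n_missing = sum(!called),
                 n_truth_overlap = nrow(cc),
                 het_to_hom = het_to_hom, hom_to_het = hom_to_het,
                 min_depth = as.integer(min_depth)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Genotype concordance (depth >=", x$min_depth, ")\n")
  print.data.frame(x$by_genotype, digits = 4, row.names = FALSE)
  cat(sprintf("aggregate accuracy %.4f over %d calls (%d missing)\n",
              x$accuracy, x$n_compared, x$n_missing))
  cat("errors: het->hom", x$het_to_hom, "; hom->het", x$hom_to_het, "\n")
  invisible(x)
}

#' Call accuracy across read-depth thresholds
#'
#' Recomputes aggregate concordance while sweeping the minimum-depth filter,
#' as used to compare callers across coverage regimes.
#'
#' @inheritParams concordance_by_genotype
#' @param depth_grid Ascending integer vector of minimum depths.
#' @return Data frame with one row per threshold: `min_depth`, `accuracy`,
#'   `n_calls`, `n_missing`.
#' @export
accuracy_vs_depth <- function(calls, truth, depth_grid = c(10, 20, 30)) {
  if (length(depth_grid) == 0L) stop("`depth_grid` must be non-empty")
  if (is.unsorted(depth_grid)) stop("`depth_grid` must be ascending")
  rows <- lapply(depth_grid, function(d) {
    cb <- concordance_by_genotype(calls, truth, min_depth = d)
    data.frame(min_depth = d, accuracy = cb$accuracy,
               n_calls = cb$n_compared, n_missing = cb$n_missing)
  })
  do.call(rbind, rows)
}

#' Dosage concordance against integer truth genotypes
#'
#' Fraction of truth-covered sites at which the dosage, rounded to the
#' nearest integer (halves away from zero), equals the truth genotype.
#'
#' @param dosages Data frame with columns `site_id` and `dosage` (a
#'   `genotype_calls` object works directly).
#' @param truth Truth genotypes as in [concordance_by_genotype()].
#' @return Scalar concordance in \[0, 1\].
#' @export
dosage_concordance <- function(dosages, truth) {
  truth <- as_truth_vector(truth)
  if (!all(c("site_id", "dosage") %in% names(dosages)))
    stop("`dosages` needs columns site_id and dosage")
  if (any(dosages$dosage < 0 | dosages$dosage > 2))
    stop("`dosage` must lie in [0, 2]")
  keep <- dosages$site_id %in% names(truth)
  d <- dosages[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("no sites overlap the truth set")
  rounded <- floor(d$dosage + 0.5) # half away from zero on [0, 2]
  mean(rounded == unname(truth[d$site_id]))
}

as_truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    if (!all(c("site_id", "genotype") %in% names(truth)))
      stop("truth data frame needs columns site_id and genotype")
    truth <- setNames(as.integer(truth$genotype), truth$site_id)
  }
  if (is.null(names(truth)))
    stop("`truth` must be named by site_id")
  if (anyDuplicated(names(truth)))
    stop("duplicated site_id in `truth`")
  storage.mode(truth) <- "integer"
  if (any(!truth %in% 0:2))
    stop("truth genotypes must be 0, 1 or 2")
  truth
}
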