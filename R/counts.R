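#' Construct a per-site allele-count table
#'
#' The central data container: one row per biallelic SNP with the number of
#' reads supporting the alternative allele (`n_alt`) and the total reads
#' overlapping the site (`n_total`). Site identity is `chrom:pos:ref:alt`
#' with 1-based positions. Counts are assumed strand-collapsed, as produced
#' by pileup-style extraction upstream of this package.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Single-base reference and alternative alleles.
#' @param n_alt,n_total Non-negative integer read counts, `n_alt <= n_total`.
#' @param eaf Optional effect (alternative) allele frequency in \[0, 1\],
#'   used by [filter_sites()] and the Hardy-Weinberg prior mode.
#' @return A `data.frame` with a `site_id` column, one row per site.
#' @export
allele_counts <- function(chrom, pos, ref, alt, n_alt, n_total, eaf = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   n_alt = as.integer(n_alt), n_total = as.integer(n_total),
                   stringsAsFactors = FALSE)
  if (!is.null(eaf)) df$eaf <- as.numeric(eaf)
  df$site_id <- site_id(df)
  validate_counts(df)
}

site_id <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Validate an allele-count table
#'
#' Checks the count invariants (`0 <= n_alt <= n_total`, integer counts,
#' unique sites) and fills in `site_id` if the positional columns are
#' present. Tables violating an invariant are rejected with the offending
#' row identified, never silently coerced.
#'
#' @param counts Data frame with at least `n_alt` and `n_total` columns.
#' @return The validated data frame (invisibly modified: `site_id` added).
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts))
    stop("`counts` must be a data.frame")
  need <- c("n_alt", "n_total")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("`counts` lacks column(s): ", paste(miss, collapse = ", "))
  for (cl in need) {
    v <- counts[[cl]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)))
      stop("column `", cl, "` must be non-missing integers")
    counts[[cl]] <- as.integer(v)
  }
  bad <- which(counts$n_alt < 0L | counts$n_total < 0L |
               counts$n_alt > counts$n_total)
  if (length(bad))
    stop("count invariant 0 <= n_alt <= n_total violated at row ", bad[1L])
  if (is.null(counts$site_id) &&
      all(c("chrom", "pos", "ref", "alt") %in% names(counts)))
    counts$site_id <- site_id(counts)
  if (!is.null(counts$site_id) && anyDuplicated(counts$site_id))
    stop("duplicated site_id: ",
         counts$site_id[duplicated(counts$site_id)][1L])
  counts
}
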