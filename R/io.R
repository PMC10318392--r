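#' Read a per-site allele-count table
#'
#' Reads the package's tab-separated counts format: header columns `chrom`,
#' `pos` (1-based), `ref`, `alt`, `n_alt`, `n_total`, optionally `eaf`.
#' Rows violating the count invariant or duplicating a site are rejected
#' with the offending line reported.
#'
#' @param path File path.
#' @return Allele-count `data.frame` (see [allele_counts()]).
#' @export
read_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "pos", "ref", "alt", "n_alt", "n_total")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("counts table lacks column(s): ", paste(miss, collapse = ", "))
  for (cl in c("pos", "n_alt", "n_total")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(v)) || any(v != floor(v)))
      stop("non-integer `", cl, "` at line ",
           which(is.na(v) | v != floor(v))[1L] + 1L, " of ", path)
    df[[cl]] <- as.integer(v)
  }
  bad <- which(df$n_alt > df$n_total | df$n_alt < 0L)
  if (length(bad))
    stop("n_alt > n_total at line ", bad[1L] + 1L, " of ", path)
  df$site_id <- site_id(df)
  dup <- which(duplicated(df$site_id))
  if (length(dup))
    stop("duplicate site at line ", dup[1L] + 1L, " of ", path)
  validate_counts(df)
}

#' Write a per-site allele-count table
#'
#' @param counts Allele-count table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  cols <- intersect(c("chrom", "pos", "ref", "alt", "n_alt", "n_total",
                      "eaf"), names(counts))
  write.table(counts[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions to exclude
#'
#' Standard BED semantics: 0-based half-open intervals, first three columns
#' `chrom`, `start`, `end`; further columns ignored.
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t")
  if (any(vapply(parts, length, 1L) < 3L))
    stop("malformed BED line ",
         which(vapply(parts, length, 1L) < 3L)[1L], " in ", path)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end)) || any(end < start))
    stop("malformed BED coordinates in ", path)
  data.frame(chrom = vapply(parts, `[[`, "", 1L), start = start,
             end = end, stringsAsFactors = FALSE)
}

#' Filter sites by allele frequency and exclusion regions
#'
#' Applies the standard site filters before calling or benchmarking: keep
#' sites whose effect allele frequency is strictly greater than `min_eaf`
#' (default 0.01), and drop sites falling inside any exclusion interval
#' (e.g. regions of known mapping bias). BED intervals are 0-based
#' half-open; a 1-based site position `p` is excluded when
#' `start < p <= end` on the same chromosome.
#'
#' @param counts Allele-count table with `chrom` and `pos` columns.
#' @param eaf Optional numeric vector of allele frequencies (defaults to
#'   `counts$eaf`); if absent entirely, the frequency filter is skipped.
#' @param min_eaf Strict lower bound on EAF (sites with `eaf <= min_eaf`
#'   are removed).
#' @param exclude Optional exclusion intervals: a BED path or a data frame
#'   from [read_bed()].
#' @return The filtered allele-count table.
#' @export
filter_sites <- function(counts, eaf = NULL, min_eaf = 0.01,
                         exclude = NULL) {
  counts <- validate_counts(counts)
  keep <- rep(TRUE, nrow(counts))
  if (is.null(eaf)) eaf <- counts$eaf
  if (!is.null(eaf)) {
    eaf <- rep_len(as.numeric(eaf), nrow(counts))
    keep <- keep & !is.na(eaf) & eaf > min_eaf
  }
  if (!is.null(exclude)) {
    if (is.character(exclude)) exclude <- read_bed(exclude)
    for (i in seq_len(nrow(exclude)))
      keep <- keep & !(counts$chrom == exclude$chrom[i] &
                       counts$pos > exclude$start[i] &
                       counts$pos <= exclude$end[i])
  }
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gold-standard genotypes
#'
#' Reads truth genotypes from either a VCF (biallelic SNP records with a GT
#' field; the first sample column by default) or a TSV with columns `chrom`,
#' `pos`, `ref`, `alt`, `genotype`. Unphased and phased GT separators are
#' both accepted and mapped to the alternative-allele count; half-missing,
#' fully missing, and multi-allelic genotypes are skipped, with the skip
#' count available as `attr(x, "n_skipped")`. Truth sets lacking homozygous-
#' reference entries are fine: absent sites are simply never compared.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param sample Sample name (VCF only); default first sample column.
#' @return Named integer vector `site_id -> genotype` in 0/1/2.
#' @export
read_truth <- function(path, format = c("auto", "vcf", "tsv"),
                       sample = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "genotype")
    if (!all(need %in% names(df)))
      stop("truth TSV needs columns ", paste(need, collapse = ", "))
    if (any(!df$genotype %in% 0:2))
      stop("truth genotypes must be 0, 1 or 2")
    out <- setNames(as.integer(df$genotype), site_id(df))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- body[startsWith(body, "#CHROM")]
  if (length(hdr) != 1L) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  rec <- body[!startsWith(body, "#")]
  rec <- rec[nzchar(rec)]
  if (length(cols) < 10L) stop("VCF has no sample column: ", path)
  samp_idx <- if (is.null(sample)) 10L else {
    i <- match(sample, cols)
    if (is.na(i)) stop("sample '", sample, "' not found in ", path)
    i
  }
  fields <- strsplit(rec, "\t")
  n_skipped <- 0L
  ids <- character(0)
  gts <- integer(0)
  for (f in fields) {
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt) ||
        alt == "." || ref == alt) {
      n_skipped <- n_skipped + 1L
      next
    }
    fmt <- strsplit(f[9], ":")[[1]]
    gt_pos <- match("GT", fmt)
    if (is.na(gt_pos)) { n_skipped <- n_skipped + 1L; next }
    gt <- strsplit(f[samp_idx], ":")[[1]][gt_pos]
    al <- strsplit(gt, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".") ||
        !all(al %in% c("0", "1"))) {
      n_skipped <- n_skipped + 1L
      next
    }
    ids <- c(ids, paste(f[1], f[2], ref, alt, sep = ":"))
    gts <- c(gts, sum(al == "1"))
  }
  out <- setNames(gts, ids)
  if (anyDuplicated(ids)) stop("duplicated site in truth VCF: ", path)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write genotype calls as a single-sample VCF
#'
#' Emits VCF 4.2 with FORMAT `GT:GP:DS:DP`: the hard call (`./.` when
#' missing), the three genotype posteriors (4 decimals, renormalized to sum
#' to exactly 1 after rounding), the dosage and the read depth. Positions,
#' REF and ALT come from the site annotations, matched by `site_id`.
#'
#' @param calls A `genotype_calls` data frame.
#' @param sites Site annotations: data frame with `chrom`, `pos`, `ref`,
#'   `alt` (an allele-count table works).
#' @param sample_name Sample column name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, sites, sample_name, path) {
  if (is.null(sites$site_id)) sites$site_id <- site_id(sites)
  idx <- match(calls$site_id, sites$site_id)
  if (any(is.na(idx)))
    stop("call site without annotation: ",
         calls$site_id[is.na(idx)][1L])
  s <- sites[idx, , drop = FALSE]
  gp <- round(cbind(calls$p_g0, calls$p_g1, calls$p_g2), 4)
  # renormalize after rounding: push the residual onto the largest entry
  resid <- 1 - rowSums(gp)
  jmax <- max.col(gp, ties.method = "first")
  gp[cbind(seq_len(nrow(gp)), jmax)] <-
    gp[cbind(seq_len(nrow(gp)), jmax)] + resid
  gt <- ifelse(is.na(calls$hard_call), "./.",
               c("0/0", "0/1", "1/1")[calls$hard_call + 1L])
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tGT:GP:DS:DP\t%s:%s:%s:%d",
                  s$chrom, s$pos, calls$site_id, s$ref, s$alt, gt,
                  paste(sprintf("%.4f", gp[, 1]), sprintf("%.4f", gp[, 2]),
                        sprintf("%.4f", gp[, 3]), sep = ","),
                  sprintf("%.4f", calls$dosage), calls$n_total)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rnagt",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=GP,Number=G,Type=Float,Description=",
                  "\"Genotype posterior probabilities\">"),
           paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
                  "\"Genotype dosage\">"),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Serialize a fitted model to a plain-text file
#'
#' Writes the full posterior draw set plus the prior hyperparameters and
#' sampler configuration as a commented-header TSV, so a model learned once
#' can be reused to call genotypes in any number of samples. Numbers are
#' written with full precision (`%.17g`), making the round trip through
#' [read_fit()] exact and same-seed runs byte-identical.
#'
#' @param fit A [bb_fit()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bb_fit"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  hdr <- c("# rnagt fitted model v1",
           paste0("# chains=", fit$config$chains),
           paste0("# warmup=", fit$config$warmup),
           paste0("# keep=", fit$config$keep),
           paste0("# seed=", fit$config$seed),
           paste0("# n_sites=", fit$n_sites),
           paste0("# prior_dirichlet=", num(fit$priors$dirichlet)),
           paste0("# prior_alpha=", num(fit$priors$alpha)),
           paste0("# prior_beta=", num(fit$priors$beta)))
  m <- flat_draws(fit)
  ch <- rep(seq_len(dim(fit$draws)[2]), each = dim(fit$draws)[1])
  it <- rep(seq_len(dim(fit$draws)[1]), times = dim(fit$draws)[2])
  tab <- cbind(chain = ch, iter = it, m, loglik = as.vector(fit$loglik))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  body <- apply(tab, 1L, function(r)
    paste(c(sprintf("%d", r[1:2]), sprintf("%.17g", r[-(1:2)])),
          collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a serialized fitted model
#'
#' @param path Path written by [write_fit()].
#' @return A [bb_fit()] object (the `accept` element is not serialized).
#' @export
read_fit <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!length(hdr) || !grepl("rnagt fitted model", hdr[1]))
    stop("not a rnagt fitted-model file: ", path)
  get1 <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (length(ln) != 1L) stop("missing header field ", key, " in ", path)
    sub(paste0("# ", key, "="), "", ln)
  }
  nums <- function(key) as.numeric(strsplit(get1(key), ",")[[1]])
  tab <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                    sep = "\t", check.names = FALSE)
  chains <- as.integer(get1("chains"))
  keep <- as.integer(get1("keep"))
  if (nrow(tab) != chains * keep)
    stop("draw count does not match header in ", path)
  par_names <- c(paste0("theta[", 1:3, "]"), paste0("mu[", 1:3, "]"),
                 paste0("kappa[", 1:3, "]"))
  draws <- array(NA_real_, c(keep, chains, 9L),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 par_names))
  loglik <- matrix(NA_real_, keep, chains)
  for (ch in seq_len(chains)) {
    rows <- tab$chain == ch
    ord <- order(tab$iter[rows])
    draws[, ch, ] <- as.matrix(tab[rows, par_names, drop = FALSE])[ord, ]
    loglik[, ch] <- tab$loglik[rows][ord]
  }
  structure(list(
    draws = draws, loglik = loglik, accept = NULL,
    priors = bb_priors(nums("prior_dirichlet"), nums("prior_alpha"),
                       nums("prior_beta")),
    n_sites = as.integer(get1("n_sites")),
    config = list(chains = chains, warmup = as.integer(get1("warmup")),
                  keep = keep, seed = as.integer(get1("seed")),
                  shortfall = NULL, min_depth = NULL)),
    class = "bb_fit")
}
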