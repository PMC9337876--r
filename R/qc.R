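#' Missingness and autosome quality control
#'
#' Filters a genotype set the way SNP-array studies conventionally do:
#' first drop SNPs that are unplaced or off the autosomes (optional), then
#' SNPs whose missing fraction exceeds `max_snp_missing`, then samples
#' whose missing fraction exceeds `max_sample_missing`, re-evaluated on the
#' surviving SNP set. The SNP/sample passes are repeated until no further
#' removal occurs, which makes the filter idempotent. No minor-allele
#' frequency filter is applied; monomorphic SNPs are retained.
#'
#' @param x a [genotypes] object
#' @param max_snp_missing drop SNPs with missing fraction strictly above
#'   this (default 0.10)
#' @param max_sample_missing drop samples with missing fraction strictly
#'   above this (default 0.05)
#' @param autosomes_only drop SNPs without a position or outside
#'   chromosomes `autosomes` (default TRUE)
#' @param autosomes integer vector of autosome codes (default 1:26, sheep)
#' @return a [genotypes] object with attribute `"qc_report"`, a
#'   `qc_report` object listing counts removed per rule
#' @examples
#' g <- sim_genotypes_example()
#' q <- qc_filter(g)
#' attr(q, "qc_report")
#' @export
qc_filter <- function(x, max_snp_missing = 0.10, max_sample_missing = 0.05,
                      autosomes_only = TRUE, autosomes = 1:26) {
  stopifnot(max_snp_missing >= 0, max_snp_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1)
  n0 <- nrow(x$geno); m0 <- ncol(x$geno)
  removed_chr <- 0L
  if (autosomes_only) {
    keep <- !is.na(x$map$chr) & x$map$chr %in% autosomes &
      !is.na(x$map$pos_bp) & x$map$pos_bp > 0
    removed_chr <- sum(!keep)
    x <- x[, which(keep)]
  }
  if (ncol(x$geno) == 0L)
    stop("QC removed every SNP (non-autosomal/unplaced)")
  removed_snp <- 0L
  removed_sample <- 0L
  passes <- 0L
  repeat {
    passes <- passes + 1L
    snp_miss <- colMeans(is.na(x$geno))
    drop_snp <- snp_miss > max_snp_missing
    if (any(drop_snp)) {
      removed_snp <- removed_snp + sum(drop_snp)
      x <- x[, which(!drop_snp)]
      if (ncol(x$geno) == 0L)
        stop("QC removed every SNP (missingness > ", max_snp_missing, ")")
    }
    samp_miss <- rowMeans(is.na(x$geno))
    drop_samp <- samp_miss > max_sample_missing
    if (any(drop_samp)) {
      removed_sample <- removed_sample + sum(drop_samp)
      x <- x[which(!drop_samp), ]
      if (nrow(x$geno) == 0L)
        stop("QC removed every sample (missingness > ", max_sample_missing, ")")
    }
    if (!any(drop_snp) && !any(drop_samp)) break
  }
  rep <- structure(list(
    n_samples_in = n0, n_snps_in = m0,
    removed_nonautosomal = removed_chr,
    removed_snp_missing = removed_snp,
    removed_sample_missing = removed_sample,
    n_samples_out = nrow(x$geno), n_snps_out = ncol(x$geno),
    max_snp_missing = max_snp_missing,
    max_sample_missing = max_sample_missing,
    passes = passes), class = "qc_report")
  attr(x, "qc_report") <- rep
  x
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  input: %d samples x %d SNPs\n", x$n_samples_in, x$n_snps_in))
  cat(sprintf("  removed non-autosomal/unplaced SNPs: %d\n",
              x$removed_nonautosomal))
  cat(sprintf("  removed SNPs (missing > %.2f): %d\n",
              x$max_snp_missing, x$removed_snp_missing))
  cat(sprintf("  removed samples (missing > %.2f): %d\n",
              x$max_sample_missing, x$removed_sample_missing))
  cat(sprintf("  output: %d samples x %d SNPs (%d pass(es))\n",
              x$n_samples_out, x$n_snps_out, x$passes))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` (from `attr(x, "qc_report")`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(rule = names(unclass(report)),
                   value = unlist(unclass(report), use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Merge two genotype datasets on their common SNPs
#'
#' Samples are concatenated; the marker set is the intersection of SNP ids
#' whose alleles can be reconciled. For a shared SNP, `b`'s codes are kept
#' as-is when alleles match, recoded `2 - g` when A1/A2 are swapped, and
#' strand-flipped (allele complement) when that reconciles them -- except
#' for strand-ambiguous A/T and C/G SNPs, which are dropped whenever a
#' flip would be needed. SNPs with irreconcilable alleles or mismatching
#' chromosome/position are dropped and counted in the attached report.
#'
#' @param a,b [genotypes] objects on the same genome build
#' @return a [genotypes] object (map taken from `a`) with attribute
#'   `"merge_report"`
#' @export
merge_datasets <- function(a, b) {
  if (length(intersect(a$samples$sample_id, b$samples$sample_id)) > 0L)
    stop("duplicate sample_ids across datasets")
  common <- intersect(a$map$snp_id, b$map$snp_id)
  if (length(common) == 0L) stop("zero overlapping SNPs")
  ia <- match(common, a$map$snp_id)
  ib <- match(common, b$map$snp_id)
  ma <- a$map[ia, ]; mb <- b$map[ib, ]
  pos_ok <- !is.na(ma$chr) & !is.na(mb$chr) &
    ma$chr == mb$chr & ma$pos_bp == mb$pos_bp
  direct <- ma$a1 == mb$a1 & ma$a2 == mb$a2
  swapped <- ma$a1 == mb$a2 & ma$a2 == mb$a1 & !direct
  ca1 <- unname(.complement[mb$a1]); ca2 <- unname(.complement[mb$a2])
  flip_direct <- !is.na(ca1) & !is.na(ca2) & ma$a1 == ca1 & ma$a2 == ca2
  flip_swapped <- !is.na(ca1) & !is.na(ca2) & ma$a1 == ca2 & ma$a2 == ca1
  ambiguous <- !is.na(ca1) & (mb$a1 == ca2)  # A/T or C/G pair
  use_flip <- (flip_direct | flip_swapped) & !direct & !swapped
  keep <- pos_ok & (direct | swapped | (use_flip & !ambiguous))
  n_amb <- sum(pos_ok & use_flip & ambiguous)
  n_conflict <- sum(pos_ok & !(direct | swapped | use_flip))
  n_pos <- sum(!pos_ok)
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) == 0L) stop("zero overlapping SNPs after allele checks")
  recode <- (swapped | flip_swapped)[keep]
  gb <- b$geno[, ib, drop = FALSE]
  if (any(recode))
    gb[, recode] <- 2L - gb[, recode, drop = FALSE]
  out <- structure(list(
    geno = rbind(a$geno[, ia, drop = FALSE], gb),
    map = { m <- a$map[ia, ]; rownames(m) <- NULL; m },
    samples = { s <- rbind(a$samples, b$samples); rownames(s) <- NULL; s }),
    class = "genotypes")
  attr(out, "merge_report") <- list(
    n_common = length(common), n_kept = length(ia),
    n_recoded = sum(recode), n_strand_ambiguous_dropped = n_amb,
    n_allele_conflict_dropped = n_conflict, n_position_mismatch = n_pos)
  out
}
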