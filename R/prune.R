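# Squared dosage correlation (Rogers-Huff style, unphased) for two genotype
# vectors over pairwise-complete samples. NA when either SNP is monomorphic
# on the complete subset or fewer than min_n complete pairs remain.
dosage_r2 <- function(g1, g2, min_n = 10L) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < min_n) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Removes SNPs in high linkage disequilibrium the way PLINK's
#' `--indep-pairwise` does: windows of `window_snps` SNPs advance by
#' `step_snps` along each chromosome; within a window, while any pair of
#' retained SNPs has squared dosage correlation above `r2_threshold`, one
#' SNP of the offending pair is removed. Removal is deterministic: the
#' highest-r2 pair is resolved first (ties by marker order) and the SNP
#' with the higher missing rate is dropped (ties: the later marker).
#' r2 uses pairwise-complete samples; pairs with fewer than `min_pair_n`
#' complete samples, or involving a SNP that is monomorphic on the
#' complete subset, are skipped. SNPs on different chromosomes are never
#' compared.
#'
#' @param x a [genotypes] object sorted by (chr, pos)
#' @param window_snps window size in SNPs (default 50)
#' @param step_snps window increment in SNPs (default 5)
#' @param r2_threshold removal threshold on r2 (default 0.1)
#' @param min_pair_n minimum pairwise-complete samples for an r2 value
#' @return the pruned [genotypes] object; attribute `"pruned_out"` holds
#'   the removed snp_ids
#' @export
ld_prune <- function(x, window_snps = 50L, step_snps = 5L,
                     r2_threshold = 0.1, min_pair_n = 10L) {
  if (window_snps < step_snps) stop("window_snps must be >= step_snps")
  if (window_snps < 2L) stop("window_snps must be >= 2")
  keep <- rep(TRUE, ncol(x$geno))
  miss <- colMeans(is.na(x$geno))
  for (ch in unique(x$map$chr)) {
    idx <- which(x$map$chr == ch)
    if (length(idx) < 2L) next
    starts <- seq.int(1L, max(1L, length(idx) - 1L), by = step_snps)
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1L, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2L) next
      G <- x$geno[, w, drop = FALSE]
      r2 <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs")^2)
      nobs <- crossprod(!is.na(G))
      r2[nobs < min_pair_n] <- NA
      diag(r2) <- NA
      repeat {
        if (all(is.na(r2)) || max(r2, na.rm = TRUE) <= r2_threshold) break
        hit <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
        i <- w[hit[1]]; j <- w[hit[2]]
        drop <- if (miss[i] > miss[j]) hit[1] else hit[2]
        keep[w[drop]] <- FALSE
        r2[drop, ] <- NA
        r2[, drop] <- NA
      }
    }
  }
  out <- x[, which(keep)]
  attr(out, "pruned_out") <- x$map$snp_id[!keep]
  out
}
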