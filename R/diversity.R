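# Unbiased per-SNP expected heterozygosity 2*p*q * 2n/(2n-1) from a
# genotype submatrix (rows = individuals of one population).
.he_by_snp <- function(g) {
  n <- colSums(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  he <- 2 * p * (1 - p) * (2 * n) / pmax(2 * n - 1, 1)
  he[n == 0L] <- NA_real_
  he
}

.se <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(0)
  stats::sd(v) / sqrt(length(v))
}

#' Per-breed diversity statistics
#'
#' Observed heterozygosity (Ho) is the per-individual fraction of
#' heterozygous calls among non-missing genotypes, averaged over the
#' breed's individuals (SE over individuals). Expected heterozygosity (He)
#' is the per-SNP unbiased estimate `2*p*(1-p) * 2n/(2n-1)` from the
#' breed's allele frequencies, averaged over all SNPs including
#' monomorphic ones (SE over SNPs). F_IS is the per-individual
#' method-of-moments coefficient
#' `(O_hom - E_hom) / (L_obs - E_hom)`, where `E_hom` sums `1 - He_j` over
#' the SNPs observed in that individual, averaged over individuals
#' (SE over individuals). This mirrors the per-population PLINK
#' `--het`-style bookkeeping.
#'
#' @param x a [genotypes] object
#' @param breed breed code (must have >= 2 samples)
#' @return one-row data frame: `breed`, `n`, `ho_mean`, `ho_se`, `he_mean`,
#'   `he_se`, `fis_mean`, `fis_se`
#' @export
breed_diversity <- function(x, breed) {
  idx <- breed_rows(x, breed, min_n = 2L)
  g <- x$geno[idx, , drop = FALSE]
  if (all(is.na(g))) stop("breed ", breed, " has no observed genotypes")
  ho_i <- rowMeans(g == 1L, na.rm = TRUE)
  he_j <- .he_by_snp(g)
  obs <- !is.na(g)
  hom <- obs & g != 1L
  e_hom_j <- 1 - he_j
  e_hom_i <- as.vector(obs %*% ifelse(is.na(e_hom_j), 0, e_hom_j))
  l_obs <- rowSums(obs & rep(!is.na(e_hom_j), each = nrow(g)))
  o_hom <- rowSums(hom)
  denom <- l_obs - e_hom_i
  fis_i <- ifelse(abs(denom) < .Machine$double.eps, NA_real_,
                  (o_hom - e_hom_i) / denom)
  data.frame(breed = breed, n = length(idx),
             ho_mean = mean(ho_i, na.rm = TRUE), ho_se = .se(ho_i),
             he_mean = mean(he_j, na.rm = TRUE), he_se = .se(he_j),
             fis_mean = mean(fis_i, na.rm = TRUE), fis_se = .se(fis_i),
             stringsAsFactors = FALSE)
}

#' Diversity table over all breeds
#'
#' @param x a [genotypes] object
#' @param breeds breed codes (default: all with >= 2 samples)
#' @return data frame, one [breed_diversity()] row per breed
#' @export
diversity_table <- function(x, breeds = NULL) {
  if (is.null(breeds)) {
    tb <- table(x$samples$breed)
    breeds <- names(tb)[tb >= 2L]
  }
  do.call(rbind, lapply(breeds, function(b) breed_diversity(x, b)))
}

# Weir-Cockerham (1984) variance components a, b, c per SNP for two
# populations; inputs are per-SNP vectors. Returns a list of components.
.wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# per-SNP counts/frequencies for one breed subset
.pop_snp_stats <- function(g) {
  n <- colSums(!is.na(g))
  list(n = n,
       p = colMeans(g, na.rm = TRUE) / 2,
       h = colMeans(g == 1L, na.rm = TRUE))
}

#' Pairwise F_ST between two breeds
#'
#' Default is the Weir-Cockerham (1984) two-population estimator combined
#' across SNPs as a ratio of sums of the variance components,
#' `sum(a) / sum(a + b + c)`. SNPs monomorphic across both breeds, or with
#' fewer than two genotyped individuals in either breed, are excluded.
#' Negative estimates are reported as computed. `method = "hudson"` gives
#' the Hudson estimator (ratio of averages of the Bhatia et al.
#' numerator/denominator).
#'
#' @param x a [genotypes] object
#' @param breed_a,breed_b breed codes (>= 2 samples each)
#' @param method `"wc"` (default) or `"hudson"`
#' @return a single F_ST value
#' @export
pairwise_fst <- function(x, breed_a, breed_b, method = c("wc", "hudson")) {
  method <- match.arg(method)
  ia <- breed_rows(x, breed_a, min_n = 2L)
  ib <- breed_rows(x, breed_b, min_n = 2L)
  sa <- .pop_snp_stats(x$geno[ia, , drop = FALSE])
  sb <- .pop_snp_stats(x$geno[ib, , drop = FALSE])
  pool <- (sa$n * sa$p + sb$n * sb$p) / (sa$n + sb$n)
  use <- sa$n >= 2L & sb$n >= 2L & !is.na(pool) & pool > 0 & pool < 1
  if (!any(use)) stop("no usable (polymorphic) SNPs for this breed pair")
  if (method == "wc") {
    w <- .wc_components(sa$n[use], sb$n[use], sa$p[use], sb$p[use],
                        sa$h[use], sb$h[use])
    sum(w$a) / sum(w$a + w$b + w$c)
  } else {
    m1 <- 2 * sa$n[use]; m2 <- 2 * sb$n[use]
    p1 <- sa$p[use]; p2 <- sb$p[use]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num) / sum(den)
  }
}

#' All pairwise F_ST values plus per-breed means
#'
#' @inheritParams pairwise_fst
#' @param breeds breed codes (default: all with >= 2 samples)
#' @return an `fst_matrix` object: list with the symmetric `fst` matrix
#'   (zero diagonal) and `mfst`, each breed's mean off-diagonal F_ST
#' @export
fst_matrix <- function(x, breeds = NULL, method = c("wc", "hudson")) {
  method <- match.arg(method)
  if (is.null(breeds)) {
    tb <- table(x$samples$breed)
    breeds <- names(tb)[tb >= 2L]
  }
  k <- length(breeds)
  if (k < 2L) stop("need at least two breeds")
  m <- matrix(0, k, k, dimnames = list(breeds, breeds))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      m[i, j] <- m[j, i] <- pairwise_fst(x, breeds[i], breeds[j], method)
    }
  }
  structure(list(fst = m, mfst = mean_fst(m)), class = "fst_matrix")
}

#' Mean F_ST of a breed over its pairwise values
#'
#' @param m an `fst_matrix` object or a symmetric numeric matrix with
#'   breed dimnames
#' @param breed breed code; when `NULL`, a named vector for all breeds
#' @return mean of the breed's off-diagonal entries
#' @export
mean_fst <- function(m, breed = NULL) {
  if (inherits(m, "fst_matrix")) m <- m$fst
  if (nrow(m) < 2L) stop("F_ST matrix with a single breed has no mean")
  mf <- vapply(seq_len(nrow(m)), function(i) mean(m[i, -i]), numeric(1))
  names(mf) <- rownames(m)
  if (is.null(breed)) mf else {
    if (!breed %in% names(mf)) stop("breed not in matrix: ", breed)
    unname(mf[breed])
  }
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise F_ST (", nrow(x$fst), " breeds)\n", sep = "")
  print(round(x$fst, digits))
  cat("Mean F_ST per breed:\n")
  print(round(x$mfst, digits))
  invisible(x)
}

#' Per-population A2 allele frequencies
#'
#' @param x a [genotypes] object
#' @param breeds breed codes (default all)
#' @return matrix SNPs x populations of A2 allele frequencies (NA where a
#'   population has no calls at a SNP)
#' @export
allele_freqs <- function(x, breeds = NULL) {
  if (is.null(breeds)) breeds <- unique(x$samples$breed)
  f <- vapply(breeds, function(b) {
    g <- x$geno[x$samples$breed == b, , drop = FALSE]
    colMeans(g, na.rm = TRUE) / 2
  }, numeric(ncol(x$geno)))
  f <- matrix(f, nrow = ncol(x$geno), dimnames = list(x$map$snp_id, breeds))
  f
}

#' Nei (1972) standard genetic distance between populations
#'
#' From biallelic A2 allele frequencies, per population pair:
#' `D = -ln( Jxy / sqrt(Jx * Jy) )`, with gene identities
#' `Jx = sum(p^2 + q^2)`, `Jxy = sum(p1*p2 + q1*q2)` accumulated over all
#' loci (pairwise-complete) before the ratio. `method = "reynolds"` gives
#' the drift-based Reynolds distance `-ln(1 - theta)` with
#' `theta = sum((p1-p2)^2) / sum(1 - p1*p2 - q1*q2)`, an alternative for
#' pure-drift divergence.
#'
#' @param freqs matrix loci x populations of A2 allele frequencies in
#'   \[0, 1\] (e.g. from [allele_freqs()])
#' @param method `"nei"` (default) or `"reynolds"`
#' @return symmetric nonnegative distance matrix with zero diagonal
#' @export
nei_distance <- function(freqs, method = c("nei", "reynolds")) {
  method <- match.arg(method)
  freqs <- as.matrix(freqs)
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  pops <- colnames(freqs)
  if (is.null(pops)) pops <- paste0("pop", seq_len(ncol(freqs)))
  k <- ncol(freqs)
  if (any(colSums(!is.na(freqs)) == 0L))
    stop("population with undefined frequencies at every locus")
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      p1 <- freqs[, i]; p2 <- freqs[, j]
      ok <- !is.na(p1) & !is.na(p2)
      if (!any(ok))
        stop("no shared defined loci for populations ", pops[i], "/", pops[j])
      p1 <- p1[ok]; p2 <- p2[ok]
      q1 <- 1 - p1; q2 <- 1 - p2
      if (method == "nei") {
        jx <- sum(p1^2 + q1^2)
        jy <- sum(p2^2 + q2^2)
        jxy <- sum(p1 * p2 + q1 * q2)
        d[i, j] <- d[j, i] <- -log(jxy / sqrt(jx * jy))
      } else {
        theta <- sum((p1 - p2)^2) / sum(1 - p1 * p2 - q1 * q2)
        d[i, j] <- d[j, i] <- -log(1 - theta)
      }
    }
  }
  d
}

#' Genotype PCA with Patterson scaling
#'
#' Each SNP column is centered by twice its allele frequency and scaled by
#' `sqrt(p*(1-p))`; missing cells contribute zero after centering (mean
#' imputation). Monomorphic SNPs are dropped. The sample-by-sample
#' covariance is eigendecomposed; per-component variance fractions are
#' reported as percentages of the total positive spectrum.
#'
#' @param x a [genotypes] object with >= 3 samples and >= 2 polymorphic SNPs
#' @param k number of components to return (default 10, capped at n-1)
#' @return a `pca_result`: list with `coords` (samples x k eigenvector
#'   coordinates), `varfrac` (percent variance per returned component),
#'   `eigenvalues` (full positive spectrum) and the sample table
#' @export
snp_pca <- function(x, k = 10L) {
  if (nrow(x$geno) < 3L) stop("PCA needs at least 3 samples")
  g <- x$geno
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("PCA needs at least 2 polymorphic SNPs")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  xs <- sweep(g, 2L, 2 * p)
  xs <- sweep(xs, 2L, sqrt(p * (1 - p)), "/")
  xs[is.na(xs)] <- 0
  cv <- tcrossprod(xs) / ncol(xs)
  eig <- eigen(cv, symmetric = TRUE)
  pos <- eig$values > 1e-12 * max(eig$values)
  total <- sum(eig$values[pos])
  k <- min(k, sum(pos))
  coords <- eig$vectors[, seq_len(k), drop = FALSE]
  rownames(coords) <- x$samples$sample_id
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coords = coords,
                 varfrac = 100 * eig$values[seq_len(k)] / total,
                 eigenvalues = eig$values[pos],
                 samples = x$samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components returned\n",
              nrow(x$coords), ncol(x$coords)))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", utils::head(x$varfrac, 5)), collapse = ", "),
      if (length(x$varfrac) > 5) "...\n" else "\n")
  invisible(x)
}
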