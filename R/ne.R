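#' Haldane map function and its inverse
#'
#' Converts genetic distance d (Morgans) to recombination fraction
#' `c = 0.5 * (1 - exp(-2d))` and back.
#'
#' @param d genetic distance in Morgans
#' @return recombination fraction in \[0, 0.5)
#' @export
haldane_c <- function(d) 0.5 * (1 - exp(-2 * d))

#' @rdname haldane_c
#' @param c recombination fraction in \[0, 0.5)
#' @export
haldane_d <- function(c) -0.5 * log(1 - 2 * c)

#' Recombination-binned mean r-squared
#'
#' The LD backbone for effective-population-size estimation. Physical
#' distance between within-chromosome SNP pairs is mapped to a
#' recombination fraction c through a uniform genetic map
#' (`rate_cM_per_Mb`) and Haldane's function; pairs are binned on a c
#' grid. Within each bin, up to `max_pairs_per_bin` pairs are drawn
#' uniformly (deterministically for a given `seed`) and the squared
#' dosage correlation is computed on pairwise-complete samples. Bins with
#' fewer than `min_pairs` usable pairs are flagged unusable. Pairs
#' involving a monomorphic SNP or fewer than 10 complete samples are
#' skipped.
#'
#' @param x a [genotypes] object
#' @param breed restrict to one breed (default: use all samples);
#'   requires >= 10 individuals
#' @param c_edges bin edges on the recombination-fraction scale
#' @param rate_cM_per_Mb uniform genetic-map rate (default 1.0)
#' @param max_pairs_per_bin subsampling cap per bin (default 2000)
#' @param min_pairs minimum usable pairs for a bin to count (default 500)
#' @param seed subsampling seed (recorded in the output)
#' @return data frame of class `recomb_bins`: `c_low`, `c_high`, `c_mid`
#'   (mean Haldane c of the aggregated pairs), `r2_mean`, `n_pairs`,
#'   `n_samples`, `usable`; the seed is kept as an attribute
#' @export
binned_r2 <- function(x, breed = NULL,
                      c_edges = c(0.001, 0.002, 0.005, 0.01, 0.02,
                                  0.05, 0.1, 0.25),
                      rate_cM_per_Mb = 1.0, max_pairs_per_bin = 2000L,
                      min_pairs = 500L, seed = 1L) {
  if (!is.null(breed)) {
    idx <- breed_rows(x, breed, min_n = 10L)
    x <- x[idx, ]
  } else if (nrow(x$geno) < 10L) {
    stop("need at least 10 individuals for LD binning")
  }
  stopifnot(all(diff(c_edges) > 0), c_edges[1] > 0,
            utils::tail(c_edges, 1) <= 0.5)
  set.seed(derive_seed(seed, "binned_r2"))
  # monomorphic or near-unobserved SNPs carry no LD information; drop them
  # from the pair universe before subsampling so the pair budget is spent
  # on informative pairs
  p <- colMeans(x$geno, na.rm = TRUE) / 2
  nobs <- colSums(!is.na(x$geno))
  poly <- which(!is.na(p) & p > 0 & p < 1 & nobs >= 10L)
  if (length(poly) < 2L) stop("fewer than 2 usable polymorphic SNPs")
  x <- x[, poly]
  n_ind <- nrow(x$geno)
  m_per_bp <- rate_cM_per_Mb * 1e-8
  d_edges_bp <- haldane_d(c_edges) / m_per_bp
  nbin <- length(c_edges) - 1L
  res <- data.frame(c_low = c_edges[-length(c_edges)],
                    c_high = c_edges[-1],
                    c_mid = NA_real_, r2_mean = NA_real_,
                    n_pairs = 0L, n_samples = n_ind, usable = FALSE)
  chroms <- unique(x$map$chr)
  for (b in seq_len(nbin)) {
    lo <- d_edges_bp[b]; hi <- d_edges_bp[b + 1]
    # per chromosome: for SNP i, partners j with pos_j - pos_i in (lo, hi]
    cand <- list(); cnt_all <- integer(0); base_all <- integer(0)
    meta <- list()
    for (ch in chroms) {
      snp_idx <- which(x$map$chr == ch)
      pos <- x$map$pos_bp[snp_idx]
      if (length(pos) < 2L) next
      hi_cnt <- findInterval(pos + hi, pos)
      lo_cnt <- findInterval(pos + lo, pos)
      cnt <- hi_cnt - lo_cnt
      keep <- cnt > 0L
      if (!any(keep)) next
      meta[[length(meta) + 1L]] <-
        list(snp_idx = snp_idx, which_i = which(keep),
             base = lo_cnt[keep], cnt = cnt[keep])
    }
    if (length(meta) == 0L) next
    cnt_all <- unlist(lapply(meta, `[[`, "cnt"))
    total <- sum(cnt_all)
    sel <- if (total > max_pairs_per_bin)
      sort(sample.int(total, max_pairs_per_bin)) else seq_len(total)
    # decode flat pair index -> (chromosome block, i, j)
    cum <- cumsum(cnt_all)
    block_sizes <- vapply(meta, function(m) length(m$cnt), integer(1))
    block_of <- rep(seq_along(meta), block_sizes)
    islot <- findInterval(sel - 1L, cum) + 1L
    offset <- sel - c(0L, cum)[islot]
    r2v <- numeric(length(sel)); cv <- numeric(length(sel))
    within <- islot - c(0L, cumsum(block_sizes))[block_of[islot]]
    for (k in seq_along(sel)) {
      m <- meta[[block_of[islot[k]]]]
      i_loc <- m$which_i[within[k]]
      j_loc <- m$base[within[k]] + offset[k]
      gi <- m$snp_idx[i_loc]; gj <- m$snp_idx[j_loc]
      r2v[k] <- dosage_r2(x$geno[, gi], x$geno[, gj])
      cv[k] <- haldane_c((x$map$pos_bp[gj] - x$map$pos_bp[gi]) * m_per_bp)
    }
    ok <- !is.na(r2v)
    res$n_pairs[b] <- sum(ok)
    if (any(ok)) {
      res$r2_mean[b] <- mean(r2v[ok])
      res$c_mid[b] <- mean(cv[ok])
    }
    res$usable[b] <- res$n_pairs[b] >= min_pairs
  }
  if (!any(res$n_pairs > 0L)) stop("no usable SNP pairs in any bin")
  attr(res, "seed") <- seed
  class(res) <- c("recomb_bins", "data.frame")
  res
}

#' Effective population size from one LD bin
#'
#' Inverts the Sved relationship `E[r2] = 1/(1 + 4*Ne*c) + 1/n` for a
#' recombination bin: the sampling contribution `1/n_samples` is
#' subtracted from the bin's mean r2 and
#' `Ne = (1/r2_adj - 1) / (4 * c_mid)`. Returns `NA` (flagged undefined)
#' when the adjusted r2 is non-positive.
#'
#' @param bin one row of a [binned_r2()] result (or any list with
#'   `r2_mean`, `c_mid`, `n_samples`)
#' @return the Ne estimate, or `NA_real_` when undefined
#' @export
ne_from_bin <- function(bin) {
  if (is.na(bin$c_mid) || bin$c_mid <= 0) stop("bin has c_mid <= 0")
  r2_adj <- bin$r2_mean - 1 / bin$n_samples
  if (is.na(r2_adj) || r2_adj <= 0) return(NA_real_)
  (1 / r2_adj - 1) / (4 * bin$c_mid)
}

#' Ne trajectory over past generations
#'
#' Each usable bin yields one point: LD at recombination fraction c
#' reflects the effective size roughly `t = 1/(2c)` generations ago, so
#' the bin grid maps to a trajectory of (generation, Ne). The trajectory
#' is truncated to `t <= max_generation` (default 50); the current Ne is
#' taken from the largest usable c bin regardless of truncation.
#'
#' @param bins a [binned_r2()] result with >= 3 usable bins
#' @param max_generation truncate the trajectory at this generation
#' @return an `ne_trajectory` data frame (`generation`, `ne`, `c_mid`,
#'   `r2_mean`, `n_pairs`), ordered by generation, with attribute
#'   `"current_ne"`
#' @export
ne_trajectory <- function(bins, max_generation = 50) {
  use <- bins[bins$usable & !is.na(bins$c_mid), , drop = FALSE]
  if (nrow(use) < 3L) stop("need at least 3 usable bins")
  use$generation <- 1 / (2 * use$c_mid)
  use$ne <- vapply(seq_len(nrow(use)), function(i)
    ne_from_bin(use[i, ]), numeric(1))
  current <- use$ne[which.max(use$c_mid)]
  use <- use[use$generation <= max_generation, , drop = FALSE]
  use <- use[order(use$generation), c("generation", "ne", "c_mid",
                                      "r2_mean", "n_pairs")]
  rownames(use) <- NULL
  attr(use, "current_ne") <- current
  class(use) <- c("ne_trajectory", "data.frame")
  use
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("LD-based Ne trajectory (", nrow(x), " points; current Ne = ",
      format(attr(x, "current_ne"), digits = 4), ")\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
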