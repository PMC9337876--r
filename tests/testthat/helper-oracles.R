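# Brute-force ROH oracle: enumerate every qualifying interval directly
# from the criteria, keep the maximal ones, select longest-first.
# g: codes 0/1/2/NA for one chromosome; pos: increasing positions.
# Returns data.frame(start_idx, end_idx, n_het, n_miss), ordered by start.
oracle_roh <- function(g, pos, params) {
  n <- length(g)
  hom <- !is.na(g) & g != 1L
  edges <- params$class_edges_bp
  gaps <- diff(pos)
  jmax <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!hom[i]) next
    js <- i:n
    len <- pos[js] - pos[i] + 1
    nsnp <- js - i + 1L
    nhet <- cumsum(g[js] == 1L & !is.na(g[js]))
    nmiss <- cumsum(is.na(g[js]))
    gap_ok <- c(TRUE, cummax(gaps[seq.int(i, length.out = n - i)]) <=
                  params$max_gap_bp)
    cls <- findInterval(len, edges)
    cls[cls < 1L] <- 1L
    ok <- hom[js] & len >= params$min_length_bp &
      nsnp >= params$l_min_snps & gap_ok &
      nsnp / len >= params$min_density_snp_per_bp &
      nhet <= params$het_allow[cls] & nmiss <= params$miss_allow[cls]
    if (any(ok)) jmax[i] <- js[max(which(ok))]
  }
  cand <- which(!is.na(jmax))
  if (length(cand) == 0L)
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      n_het = integer(), n_miss = integer()))
  # maximal: no earlier start reaches at least as far
  keep <- logical(length(cand))
  best <- -1L
  for (k in seq_along(cand)) {
    if (jmax[cand[k]] > best) {
      keep[k] <- TRUE
      best <- jmax[cand[k]]
    }
  }
  cand <- cand[keep]
  seg <- data.frame(start_idx = cand, end_idx = jmax[cand])
  seg$len <- pos[seg$end_idx] - pos[seg$start_idx] + 1
  seg <- seg[order(-seg$len, seg$start_idx), ]
  chosen <- integer(0)
  for (k in seq_len(nrow(seg))) {
    if (!any(seg$start_idx[k] <= seg$end_idx[chosen] &
             seg$start_idx[chosen] <= seg$end_idx[k]))
      chosen <- c(chosen, k)
  }
  seg <- seg[chosen, ]
  seg <- seg[order(seg$start_idx), ]
  data.frame(
    start_idx = seg$start_idx, end_idx = seg$end_idx,
    n_het = vapply(seq_len(nrow(seg)), function(k) {
      s <- seg$start_idx[k]:seg$end_idx[k]
      sum(g[s] == 1L, na.rm = TRUE)
    }, integer(1)),
    n_miss = vapply(seq_len(nrow(seg)), function(k) {
      s <- seg$start_idx[k]:seg$end_idx[k]
      sum(is.na(g[s]))
    }, integer(1)))
}

# random one-chromosome ROH fixture with planted homozygous tracts
random_roh_fixture <- function(n_snps, seed) {
  set.seed(seed)
  pos <- sort(sample.int(n_snps * 6e4, n_snps))
  p_het <- runif(1, 0.2, 0.5)
  g <- sample(c(0L, 1L, 2L), n_snps, replace = TRUE,
              prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2))
  n_tracts <- sample(0:3, 1)
  for (t in seq_len(n_tracts)) {
    a <- sample.int(n_snps - 10L, 1)
    b <- min(n_snps, a + sample.int(max(3L, n_snps %/% 3L), 1))
    g[a:b] <- sample(c(0L, 2L), b - a + 1L, replace = TRUE)
    # sprinkle occasional het/missing inside the tract
    k <- sample(0:3, 1)
    if (k > 0) {
      at <- sample(a:b, min(k, b - a + 1L))
      g[at] <- sample(c(1L, NA_integer_), length(at), replace = TRUE)
    }
  }
  miss <- runif(n_snps) < 0.01
  g[miss] <- NA_integer_
  params <- roh_params(
    l_min_snps = sample(8:25, 1),
    max_gap_bp = sample(c(2e5, 2.5e5, 4e5), 1),
    min_density_snp_per_bp = 1 / sample(c(4e4, 6e4, 8e4), 1),
    min_length_bp = sample(c(6e5, 1e6, 2e6), 1),
    class_edges_bp = c(6e5, 4e6, 8e6, 16e6))
  list(g = g, pos = pos, params = params)
}

# Greedy LD-pruning oracle for a SNP set that fits inside one window:
# repeatedly find the highest-r2 pair above the threshold (ties: first by
# index) and drop the member with the higher missing rate (ties: the
# later SNP).
oracle_prune_window <- function(g, r2_threshold, min_pair_n = 10L) {
  keep <- seq_len(ncol(g))
  miss <- colMeans(is.na(g))
  repeat {
    k <- length(keep)
    best <- NULL
    bestr2 <- r2_threshold
    for (a in seq_len(k - 1)) {
      for (b in seq.int(a + 1, k)) {
        x <- g[, keep[a]]; y <- g[, keep[b]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < min_pair_n) next
        if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next
        r2 <- cor(x[ok], y[ok])^2
        if (r2 > bestr2 + 1e-12) {
          bestr2 <- r2
          best <- c(a, b)
        }
      }
    }
    if (is.null(best)) break
    drop <- if (miss[keep[best[1]]] > miss[keep[best[2]]])
      best[1] else best[2]
    keep <- keep[-drop]
  }
  keep
}
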