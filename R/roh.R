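#' Minimum number of SNPs constituting a run of homozygosity
#'
#' False-positive-controlled threshold
#' `l = ln(alpha / (n_s * n_i)) / ln(1 - het)`, floored, with a lower
#' bound of 1. With the chance of observing `l` consecutive homozygous
#' genotypes by state alone being roughly `(1 - het)^l` per start
#' position, requiring `l` SNPs caps the expected number of spurious runs
#' across all `n_s * n_i` genotype positions at `alpha`.
#'
#' @param alpha tolerated fraction of false-positive runs, in (0, 1)
#' @param n_s number of SNPs per individual
#' @param n_i number of genotyped individuals
#' @param het mean heterozygosity across SNPs, in (0, 1)
#' @return integer SNP count, >= 1
#' @examples
#' min_snp_threshold(0.05, 470962, 211, 0.343)  # 50
#' @export
min_snp_threshold <- function(alpha, n_s, n_i, het) {
  stopifnot(alpha > 0, alpha < 1, n_s >= 1, n_i >= 1)
  if (het <= 0 || het >= 1)
    stop("het must lie strictly between 0 and 1")
  l <- floor(log(alpha / (n_s * n_i)) / log(1 - het))
  max(as.integer(l), 1L)
}

#' ROH detection parameters
#'
#' Bundles the run-of-homozygosity criteria: the derived minimum SNP count
#' (see [min_snp_threshold()]), the maximum gap between adjacent SNPs
#' inside a run, the minimum SNP density, the minimum physical length, the
#' length-class edges and the per-class heterozygote/missing allowances.
#' When a [genotypes] object is supplied, `n_s`, `n_i` and `het` default
#' to the dataset's SNP count, sample count and mean observed
#' heterozygosity across SNPs.
#'
#' @param x optional [genotypes] object used to derive `n_s`, `n_i`, `het`
#' @param alpha false-positive fraction for the SNP-count threshold
#' @param n_s,n_i,het threshold inputs; overridable individually
#' @param l_min_snps explicit minimum SNP count (overrides the formula)
#' @param max_gap_bp maximum gap between adjacent SNPs in a run (250 kb)
#' @param min_density_snp_per_bp minimum run density (1 SNP per 50 kb)
#' @param min_length_bp minimum run length (2 Mb)
#' @param class_edges_bp lower edges of the length classes
#'   (2, 4, 8, 16 Mb); classes are half-open `[2,4) [4,8) [8,16) [16,Inf)`
#' @param het_allow,miss_allow heterozygous / missing calls tolerated in a
#'   run of each class (defaults 0/1/2/4 and 2/4/8/16)
#' @return an object of class `roh_params`
#' @export
roh_params <- function(x = NULL, alpha = 0.05, n_s = NULL, n_i = NULL,
                       het = NULL, l_min_snps = NULL,
                       max_gap_bp = 250e3,
                       min_density_snp_per_bp = 1 / 50e3,
                       min_length_bp = 2e6,
                       class_edges_bp = c(2e6, 4e6, 8e6, 16e6),
                       het_allow = c(0L, 1L, 2L, 4L),
                       miss_allow = c(2L, 4L, 8L, 16L)) {
  if (!is.null(x)) {
    if (is.null(n_s)) n_s <- n_snps(x)
    if (is.null(n_i)) n_i <- n_samples(x)
    if (is.null(het)) {
      het_j <- colMeans(x$geno == 1L, na.rm = TRUE)
      het <- mean(het_j, na.rm = TRUE)
    }
  }
  if (is.null(l_min_snps)) {
    if (is.null(n_s) || is.null(n_i) || is.null(het))
      stop("supply a genotypes object, (n_s, n_i, het), or l_min_snps")
    l_min_snps <- min_snp_threshold(alpha, n_s, n_i, het)
  }
  stopifnot(length(class_edges_bp) == length(het_allow),
            length(class_edges_bp) == length(miss_allow),
            !is.unsorted(class_edges_bp, strictly = TRUE),
            min_length_bp >= class_edges_bp[1])
  structure(list(alpha = alpha, n_s = n_s, n_i = n_i, het = het,
                 l_min_snps = as.integer(l_min_snps),
                 max_gap_bp = max_gap_bp,
                 min_density_snp_per_bp = min_density_snp_per_bp,
                 min_length_bp = min_length_bp,
                 class_edges_bp = class_edges_bp,
                 het_allow = as.integer(het_allow),
                 miss_allow = as.integer(miss_allow)),
            class = "roh_params")
}

#' @export
print.roh_params <- function(x, ...) {
  cat("ROH parameters\n")
  cat(sprintf("  min SNPs per run: %d (alpha=%.3g%s)\n", x$l_min_snps,
              x$alpha,
              if (!is.null(x$het)) sprintf(", het=%.3f", x$het) else ""))
  cat(sprintf("  max gap %.0f kb; density >= 1 SNP/%.0f kb; min length %.1f Mb\n",
              x$max_gap_bp / 1e3, 1 / x$min_density_snp_per_bp / 1e3,
              x$min_length_bp / 1e6))
  cat(sprintf("  classes (Mb): %s; het allow: %s; miss allow: %s\n",
              paste(x$class_edges_bp / 1e6, collapse = "/"),
              paste(x$het_allow, collapse = "/"),
              paste(x$miss_allow, collapse = "/")))
  invisible(x)
}

.class_labels <- function(edges_bp) {
  mb <- edges_bp / 1e6
  c(paste0(utils::head(mb, -1), "-", utils::tail(mb, -1), "Mb"),
    paste0(">", utils::tail(mb, 1), "Mb"))
}

#' Detect runs of homozygosity
#'
#' Scans each individual's autosomes for maximal runs satisfying every
#' criterion in `params`: run endpoints homozygous, at least
#' `l_min_snps` SNPs and `min_length_bp` base pairs, no adjacent-SNP gap
#' above `max_gap_bp`, overall SNP density at least
#' `min_density_snp_per_bp`, and no more heterozygous/missing calls than
#' the run's length class allows. All maximal qualifying intervals (not
#' extendable to a larger qualifying interval) are enumerated, then kept
#' longest-first, dropping any that overlap an already kept run (ties by
#' leftmost start). The scan is deterministic and independent of
#' chromosome processing order.
#'
#' @param x a [genotypes] object with a position-sorted map
#' @param params a [roh_params] object; default derives the SNP-count
#'   threshold from `x`
#' @param sample_ids samples to scan (default all)
#' @return data frame of segments: `sample_id`, `chr`, `start_bp`,
#'   `end_bp` (positions of the first/last SNP, 1-based inclusive),
#'   `n_snps`, `n_het`, `n_missing`, `length_bp`, `length_class`
#' @export
detect_roh <- function(x, params = roh_params(x), sample_ids = NULL) {
  validate_genotypes(x)
  if (is.null(sample_ids)) sample_ids <- x$samples$sample_id
  rows <- match(sample_ids, x$samples$sample_id)
  if (anyNA(rows)) stop("unknown sample_id(s)")
  chroms <- unique(x$map$chr)
  labels <- .class_labels(params$class_edges_bp)
  out <- vector("list", length(rows) * length(chroms))
  k <- 0L
  for (ci in seq_along(chroms)) {
    snp_idx <- which(x$map$chr == chroms[ci])
    pos <- x$map$pos_bp[snp_idx]
    for (ri in seq_along(rows)) {
      g <- x$geno[rows[ri], snp_idx]
      g[is.na(g)] <- -1L
      seg <- roh_scan_chr(as.integer(g), as.numeric(pos),
                          params$min_length_bp, params$l_min_snps,
                          params$max_gap_bp, params$min_density_snp_per_bp,
                          params$class_edges_bp,
                          params$het_allow, params$miss_allow)
      if (nrow(seg) == 0L) next
      k <- k + 1L
      out[[k]] <- data.frame(
        sample_id = sample_ids[ri], chr = chroms[ci],
        start_bp = pos[seg[, 1] + 1L], end_bp = pos[seg[, 2] + 1L],
        n_snps = seg[, 2] - seg[, 1] + 1L,
        n_het = seg[, 3], n_missing = seg[, 4],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    res <- data.frame(sample_id = character(), chr = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric(),
                      length_class = character(), stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, out[seq_len(k)])
  res$length_bp <- res$end_bp - res$start_bp + 1
  res$length_class <- labels[findInterval(res$length_bp,
                                          params$class_edges_bp)]
  res <- res[order(match(res$sample_id, sample_ids), res$chr, res$start_bp), ]
  rownames(res) <- NULL
  res
}

# total genome length covered by SNPs: sum over chromosomes of
# (last - first SNP position + 1)
.covered_genome_bp <- function(map) {
  if (nrow(map) == 0L) stop("empty marker map")
  sum(tapply(map$pos_bp, map$chr, function(p) max(p) - min(p) + 1))
}

#' Genomic inbreeding from ROH for one individual
#'
#' `F_ROH` is the summed length of the individual's runs divided by the
#' SNP-covered autosomal genome length (per chromosome, last minus first
#' SNP position + 1, summed). Class-specific coefficients partition the
#' runs by length class and share the same denominator, so the class
#' values add up exactly to the total.
#'
#' @param segments segment rows from [detect_roh()] for one individual
#' @param map the marker map the segments were called on
#' @return one-row data frame: `froh_total` (ROH > 2 Mb) and one column
#'   per length class (`froh_2_4`, `froh_4_8`, `froh_8_16`, `froh_gt16`
#'   under the default classes)
#' @export
froh <- function(segments, map) {
  if (nrow(segments) > 0 && length(unique(segments$sample_id)) > 1L)
    stop("froh() expects segments of a single individual")
  denom <- .covered_genome_bp(map)
  edges <- c(2e6, 4e6, 8e6, 16e6)
  labels <- .class_labels(edges)
  if (nrow(segments) > 0 && "length_class" %in% names(segments) &&
      !all(segments$length_class %in% labels)) {
    # honour non-default classes carried by the segments
    labels <- unique(segments$length_class)
  }
  by_class <- vapply(labels, function(cl) {
    sum(segments$length_bp[segments$length_class == cl]) / denom
  }, numeric(1))
  out <- data.frame(froh_total = sum(segments$length_bp) / denom)
  cols <- gsub("-", "_", gsub(">", "gt", gsub("Mb$", "", labels)))
  out[paste0("froh_", cols)] <- as.list(by_class)
  out
}

#' Per-individual F_ROH table
#'
#' @param segments output of [detect_roh()] (any number of individuals)
#' @param x the [genotypes] object the segments were called on (supplies
#'   the map and the full sample list; individuals without runs get zeros)
#' @return data frame with `sample_id`, `breed`, `froh_total` and one
#'   column per length class
#' @export
froh_table <- function(segments, x) {
  denom <- .covered_genome_bp(x$map)
  edges <- c(2e6, 4e6, 8e6, 16e6)
  labels <- .class_labels(edges)
  if (nrow(segments) > 0)
    labels <- union(labels, unique(segments$length_class))
  cols <- paste0("froh_", gsub("-", "_", gsub(">", "gt",
                                              gsub("Mb$", "", labels))))
  ids <- x$samples$sample_id
  tab <- data.frame(sample_id = ids, breed = x$samples$breed,
                    froh_total = 0, stringsAsFactors = FALSE)
  for (cl in cols) tab[[cl]] <- 0
  if (nrow(segments) > 0) {
    tot <- tapply(segments$length_bp, segments$sample_id, sum) / denom
    tab$froh_total[match(names(tot), ids)] <- as.vector(tot)
    for (i in seq_along(labels)) {
      sel <- segments$length_class == labels[i]
      if (!any(sel)) next
      s <- tapply(segments$length_bp[sel], segments$sample_id[sel], sum) /
        denom
      tab[[cols[i]]][match(names(s), ids)] <- as.vector(s)
    }
  }
  tab
}

#' Breed means of F_ROH by length class
#'
#' @param ftab a [froh_table()] data frame
#' @return data frame with, per breed and per F_ROH column, the arithmetic
#'   mean and its standard error over individuals
#' @export
breed_froh <- function(ftab) {
  fcols <- grep("^froh_", names(ftab), value = TRUE)
  breeds <- unique(ftab$breed)
  out <- lapply(breeds, function(b) {
    sub <- ftab[ftab$breed == b, , drop = FALSE]
    if (nrow(sub) == 0L) stop("breed with zero individuals: ", b)
    row <- data.frame(breed = b, n = nrow(sub), stringsAsFactors = FALSE)
    for (cl in fcols) {
      row[[paste0(cl, "_mean")]] <- mean(sub[[cl]])
      row[[paste0(cl, "_se")]] <- .se(sub[[cl]])
    }
    row
  })
  do.call(rbind, out)
}

#' Export ROH segments as BED-like TSV
#'
#' Coordinates are converted to 0-based half-open (BED convention); the
#' header line flags this.
#'
#' @param segments output of [detect_roh()]
#' @param path output file
#' @return `path`, invisibly
#' @export
export_roh_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ROH segments; coordinates 0-based half-open ",
                    "(BED convention)"), con)
  bed <- data.frame(chrom = segments$chr,
                    chromStart = format(segments$start_bp - 1,
                                        scientific = FALSE, trim = TRUE),
                    chromEnd = format(segments$end_bp, scientific = FALSE,
                                      trim = TRUE),
                    name = segments$sample_id,
                    n_snps = segments$n_snps,
                    length_class = segments$length_class)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
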