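#' Diploid SNP genotype container
#'
#' Bundles a samples x SNPs matrix of allele-count codes with its marker map
#' and sample table. Codes count copies of the A2 allele: 0 (hom A1),
#' 1 (het), 2 (hom A2); missing calls are `NA`. This is the central data
#' structure consumed by all QC, diversity, ROH and Ne functions.
#'
#' @param geno integer matrix, samples in rows and SNPs in columns, values
#'   in `{0, 1, 2, NA}`. Dimnames are ignored; identity comes from `map`
#'   and `samples`.
#' @param map data frame with columns `snp_id`, `chr`, `pos_bp`, `a1`, `a2`.
#'   `chr` is the chromosome code as read from the source file; codes 1-26
#'   are treated as sheep autosomes. `pos_bp` is a 1-based physical
#'   coordinate in base pairs. Within each chromosome positions must be
#'   strictly increasing.
#' @param samples data frame with columns `sample_id`, `breed` (short breed
#'   code), and optionally `sex` (`"male"`, `"female"`, `"unknown"`) and
#'   `group` (`"island"`, `"mainland"`, `"outgroup"`); missing optional
#'   columns are filled with `"unknown"`.
#'
#' @return An object of class `"genotypes"`: a list with elements `geno`,
#'   `map` and `samples`.
#' @examples
#' g <- genotypes(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                map = data.frame(snp_id = c("s1", "s2"), chr = 1L,
#'                                 pos_bp = c(100L, 200L),
#'                                 a1 = "A", a2 = "G"),
#'                samples = data.frame(sample_id = c("i1", "i2"),
#'                                     breed = "AAA"))
#' n_snps(g)
#' @export
genotypes <- function(geno, map, samples) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_map <- c("snp_id", "chr", "pos_bp", "a1", "a2")
  miss <- setdiff(need_map, names(map))
  if (length(miss) > 0L)
    stop("map lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(c("sample_id", "breed") %in% names(samples)))
    stop("samples needs columns sample_id and breed")
  if (is.null(samples$sex)) samples$sex <- "unknown"
  if (is.null(samples$group)) samples$group <- "unknown"
  map$snp_id <- as.character(map$snp_id)
  map$chr <- as.integer(map$chr)
  map$pos_bp <- as.double(map$pos_bp)
  map$a1 <- as.character(map$a1)
  map$a2 <- as.character(map$a2)
  samples$sample_id <- as.character(samples$sample_id)
  samples$breed <- as.character(samples$breed)
  rownames(map) <- NULL
  rownames(samples) <- NULL
  obj <- structure(list(geno = geno, map = map, samples = samples),
                   class = "genotypes")
  validate_genotypes(obj)
  obj
}

validate_genotypes <- function(x) {
  if (nrow(x$geno) != nrow(x$samples))
    stop("geno has ", nrow(x$geno), " rows but samples has ",
         nrow(x$samples), " entries")
  if (ncol(x$geno) != nrow(x$map))
    stop("geno has ", ncol(x$geno), " columns but map has ",
         nrow(x$map), " entries")
  if (anyDuplicated(x$map$snp_id))
    stop("duplicate snp_id in map")
  if (anyDuplicated(x$samples$sample_id))
    stop("duplicate sample_id in sample table")
  bad <- x$geno[!is.na(x$geno)]
  if (length(bad) > 0L && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  ord <- order(x$map$chr, x$map$pos_bp)
  if (is.unsorted(ord) && !identical(ord, seq_len(nrow(x$map))))
    stop("map must be sorted by (chr, pos_bp)")
  dup_pos <- stats::ave(x$map$pos_bp, x$map$chr,
                        FUN = function(p) c(1, diff(p)))
  if (nrow(x$map) > 0L && any(dup_pos <= 0))
    stop("positions must be strictly increasing within each chromosome")
  invisible(x)
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d SNPs\n",
              nrow(x$geno), ncol(x$geno)))
  if (nrow(x$map) > 0L)
    cat(sprintf("  chromosomes: %s\n",
                paste(sort(unique(x$map$chr)), collapse = " ")))
  tb <- table(x$samples$breed)
  if (length(tb) > 0L)
    cat("  breeds: ",
        paste(sprintf("%s (%d)", names(tb), as.integer(tb)), collapse = ", "),
        "\n", sep = "")
  nm <- sum(is.na(x$geno))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              100 * nm / max(1L, length(x$geno))))
  invisible(x)
}

#' @export
summary.genotypes <- function(object, ...) {
  g <- object$geno
  out <- list(
    n_samples = nrow(g),
    n_snps = ncol(g),
    chromosomes = sort(unique(object$map$chr)),
    breeds = table(object$samples$breed),
    snp_missing = if (ncol(g)) colMeans(is.na(g)) else numeric(0),
    sample_missing = if (nrow(g)) rowMeans(is.na(g)) else numeric(0)
  )
  class(out) <- "summary.genotypes"
  out
}

#' @export
print.summary.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d SNPs on %d chromosome(s)\n",
              x$n_samples, x$n_snps, length(x$chromosomes)))
  if (x$n_snps > 0L)
    cat(sprintf("  per-SNP missingness: median %.4f, max %.4f\n",
                stats::median(x$snp_missing), max(x$snp_missing)))
  if (x$n_samples > 0L)
    cat(sprintf("  per-sample missingness: median %.4f, max %.4f\n",
                stats::median(x$sample_missing), max(x$sample_missing)))
  invisible(x)
}

#' Number of samples / SNPs
#' @param x a [genotypes] object
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$geno)

#' Subset a genotype set
#'
#' `i` selects samples, `j` selects SNPs; either may be logical, integer,
#' or character (matched against `sample_id` / `snp_id`).
#'
#' @param x a [genotypes] object
#' @param i,j sample and SNP selectors
#' @param ... ignored
#' @return a [genotypes] object
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$map$snp_id)
  if (anyNA(i) || anyNA(j)) stop("unknown sample_id or snp_id in subset")
  structure(list(geno = x$geno[i, j, drop = FALSE],
                 map = x$map[j, , drop = FALSE],
                 samples = x$samples[i, , drop = FALSE]),
            class = "genotypes") |> validate_relaxed()
}

# subsetting can reorder; only re-check shape/uniqueness, not map order
validate_relaxed <- function(x) {
  rownames(x$map) <- NULL
  rownames(x$samples) <- NULL
  if (anyDuplicated(x$samples$sample_id)) stop("duplicate sample_id")
  if (anyDuplicated(x$map$snp_id)) stop("duplicate snp_id")
  x
}

# rows of `samples` belonging to one breed; errors when absent or too small
breed_rows <- function(x, breed, min_n = 1L) {
  idx <- which(x$samples$breed == breed)
  if (length(idx) == 0L) stop("breed not present: ", breed)
  if (length(idx) < min_n)
    stop("breed ", breed, " has ", length(idx),
         " sample(s); need at least ", min_n)
  idx
}
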