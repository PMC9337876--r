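# PLINK binary codec.
#
# .bed layout (SNP-major): 3 magic bytes 0x6C 0x1B 0x01, then for each SNP
# ceiling(n_samples/4) bytes, 2 bits per sample starting at the low bits.
# Bit pairs: 00 hom A1 (code 0), 10 het (code 1), 11 hom A2 (code 2),
# 01 missing (NA). Codes count copies of A2.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: genotype code of sample slot k within a byte
.bed_lut <- local({
  decode <- c(0L, NA_integer_, 1L, 2L)
  vapply(0:3, function(k) {
    decode[bitwAnd(bitwShiftR(0:255, 2L * k), 3L) + 1L]
  }, integer(256))
})

#' Read a PLINK bed/bim/fam dataset
#'
#' Decodes the SNP-major 2-bit PLINK binary format. Genotype codes count
#' copies of the A2 allele; missing calls become `NA`. The breed code is
#' taken from the .fam family-ID column unless a sidecar sample table
#' (`<prefix>.samples.tsv` with columns `sample_id`, `breed` and optionally
#' `sex`, `group`) is present or given explicitly.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet
#' @param samples_tsv optional path to a sidecar sample table; defaults to
#'   `<prefix>.samples.tsv` when that file exists
#' @return a [genotypes] object
#' @seealso [write_plink()], [read_ped()]
#' @export
read_plink <- function(prefix, samples_tsv = NULL) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p))
      stop(errorCondition(paste0("missing PLINK file: ", p),
                          class = c("ovipop_missing_file", "error")))
  }
  bim_cols <- c("chr", "snp_id", "cm", "pos_bp", "a1", "a2")
  bim <- if (file.size(paths[2]) == 0)
    stats::setNames(data.frame("", "", 0, 0, "", "",
                               stringsAsFactors = FALSE)[0, ], bim_cols)
  else
    utils::read.table(paths[2], header = FALSE, sep = "",
                      colClasses = c("character", "character", "numeric",
                                     "numeric", "character", "character"),
                      col.names = bim_cols)
  fam_cols <- c("fid", "sample_id", "pat", "mat", "sex", "pheno")
  fam <- if (file.size(paths[3]) == 0)
    stats::setNames(data.frame(matrix("", 0, 6), stringsAsFactors = FALSE),
                    fam_cols)
  else
    utils::read.table(paths[3], header = FALSE, sep = "",
                      colClasses = "character", col.names = fam_cols)
  n <- nrow(fam)
  m <- nrow(bim)
  nbytes <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop(errorCondition(paste0("not a SNP-major PLINK .bed file: ", paths[1]),
                        class = c("ovipop_bad_magic", "error")))
  payload <- raw[-(1:3)]
  if (length(payload) != nbytes * m)
    stop(errorCondition(
      sprintf(".bed payload has %d bytes but .bim/.fam imply %d",
              length(payload), nbytes * m),
      class = c("ovipop_dim_mismatch", "error")))
  g <- matrix(NA_integer_, n, m)
  if (n > 0L && m > 0L) {
    bmat <- matrix(as.integer(payload), nrow = nbytes, ncol = m)
    for (k in 1:4) {
      if (k > n) next
      rows <- seq.int(k, n, by = 4L)
      byte_rows <- (rows - 1L) %/% 4L + 1L
      g[rows, ] <- matrix(.bed_lut[bmat[byte_rows, , drop = FALSE] + 1L, k],
                          nrow = length(rows))
    }
  }
  map <- data.frame(snp_id = bim$snp_id,
                    chr = suppressWarnings(as.integer(bim$chr)),
                    pos_bp = bim$pos_bp, a1 = bim$a1, a2 = bim$a2,
                    stringsAsFactors = FALSE)
  # non-numeric chromosome codes (X, MT, ...) are kept as NA and removed by QC
  sex <- c("1" = "male", "2" = "female")[fam$sex]
  sex[is.na(sex)] <- "unknown"
  samp <- data.frame(sample_id = fam$sample_id, breed = fam$fid,
                     sex = unname(sex), group = "unknown",
                     stringsAsFactors = FALSE)
  if (is.null(samples_tsv)) {
    cand <- paste0(prefix, ".samples.tsv")
    if (file.exists(cand)) samples_tsv <- cand
  }
  if (!is.null(samples_tsv)) {
    side <- utils::read.table(samples_tsv, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    idx <- match(samp$sample_id, side$sample_id)
    if (anyNA(idx))
      stop("sidecar sample table lacks entries for: ",
           paste(utils::head(samp$sample_id[is.na(idx)], 5), collapse = ", "))
    samp$breed <- side$breed[idx]
    if (!is.null(side$sex)) samp$sex <- side$sex[idx]
    if (!is.null(side$group)) samp$group <- side$group[idx]
  }
  obj <- structure(list(geno = g, map = map, samples = samp),
                   class = "genotypes")
  if (ncol(g) != nrow(map) || nrow(g) != nrow(samp))
    stop(errorCondition("decoded dimensions inconsistent",
                        class = c("ovipop_dim_mismatch", "error")))
  obj
}

#' Write a PLINK bed/bim/fam dataset
#'
#' Emits a SNP-major .bed with its .bim/.fam companions. Writing then
#' reading back reproduces the object exactly (the .bed payload is
#' bit-exact: trailing bits of each SNP byte block are zero-padded).
#' Sex is encoded 1/2/0 and the breed code is stored as the .fam family ID.
#'
#' @param x a [genotypes] object
#' @param prefix output path prefix
#' @param samples_tsv if `TRUE` (default) also write the
#'   `<prefix>.samples.tsv` sidecar carrying breed/sex/group
#' @return `prefix`, invisibly
#' @export
write_plink <- function(x, prefix, samples_tsv = TRUE) {
  validate_genotypes(x)
  dir <- dirname(prefix)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir)
  n <- nrow(x$geno); m <- ncol(x$geno)
  nbytes <- ceiling(n / 4)
  bits <- matrix(0L, max(nbytes, 0L), m)
  if (n > 0L && m > 0L) {
    enc <- c(0L, 2L, 3L)  # code 0/1/2 -> bit pair; NA -> 01
    for (k in 1:4) {
      if (k > n) next
      rows <- seq.int(k, n, by = 4L)
      byte_rows <- (rows - 1L) %/% 4L + 1L
      sub <- x$geno[rows, , drop = FALSE]
      code <- matrix(enc[sub + 1L], nrow = length(rows))
      code[is.na(sub)] <- 1L
      bits[byte_rows, ] <- bits[byte_rows, , drop = FALSE] +
        code * bitwShiftL(1L, 2L * (k - 1L))
    }
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  if (length(bits) > 0L) writeBin(as.raw(bits), con)
  bim <- data.frame(chr = x$map$chr, snp_id = x$map$snp_id,
                    cm = rep(0, m),
                    pos_bp = format(x$map$pos_bp, scientific = FALSE,
                                    trim = TRUE),
                    a1 = x$map$a1, a2 = x$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  sexcode <- c(male = "1", female = "2")[x$samples$sex]
  sexcode[is.na(sexcode)] <- "0"
  fam <- data.frame(fid = x$samples$breed, iid = x$samples$sample_id,
                    pat = rep("0", n), mat = rep("0", n),
                    sex = unname(sexcode), pheno = rep("-9", n))
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (isTRUE(samples_tsv)) {
    utils::write.table(
      x$samples[, c("sample_id", "breed", "sex", "group")],
      paste0(prefix, ".samples.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a text PLINK ped/map dataset
#'
#' A1 is assigned to the rarer allele (ties broken alphabetically); for
#' monomorphic SNPs the unobserved allele is recorded as `"0"`.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair
#' @return a [genotypes] object
#' @export
read_ped <- function(prefix) {
  paths <- paste0(prefix, c(".ped", ".map"))
  for (p in paths) {
    if (!file.exists(p))
      stop(errorCondition(paste0("missing PLINK file: ", p),
                          class = c("ovipop_missing_file", "error")))
  }
  map <- utils::read.table(paths[2], header = FALSE, sep = "",
                           colClasses = c("character", "character",
                                          "numeric", "numeric"),
                           col.names = c("chr", "snp_id", "cm", "pos_bp"))
  m <- nrow(map)
  lines <- readLines(paths[1])
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want))
    stop(errorCondition(
      sprintf(".ped line(s) with %s fields; expected %d for %d SNPs",
              paste(unique(lens[lens != want]), collapse = "/"), want, m),
      class = c("ovipop_dim_mismatch", "error")))
  tokm <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  al1 <- tokm[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  al2 <- tokm[, 6L + 2L * seq_len(m), drop = FALSE]
  g <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    al <- c(al1[, j], al2[, j])
    obs <- al != "0"
    tab <- sort(table(al[obs]))
    if (length(tab) > 2L)
      stop("SNP ", map$snp_id[j], " has more than two alleles")
    if (length(tab) == 0L) {
      a1[j] <- "0"; a2[j] <- "0"
    } else if (length(tab) == 1L) {
      a1[j] <- "0"; a2[j] <- names(tab)
    } else {
      if (tab[1] == tab[2]) tab <- tab[order(names(tab))]
      a1[j] <- names(tab)[1]; a2[j] <- names(tab)[2]
    }
    ok <- al1[, j] != "0" & al2[, j] != "0"
    g[ok, j] <- (al1[ok, j] == a2[j]) + (al2[ok, j] == a2[j])
  }
  sex <- c("1" = "male", "2" = "female")[tokm[, 5]]
  sex[is.na(sex)] <- "unknown"
  genotypes(g,
            map = data.frame(snp_id = map$snp_id,
                             chr = suppressWarnings(as.integer(map$chr)),
                             pos_bp = map$pos_bp, a1 = a1, a2 = a2,
                             stringsAsFactors = FALSE),
            samples = data.frame(sample_id = tokm[, 2], breed = tokm[, 1],
                                 sex = unname(sex), group = "unknown",
                                 stringsAsFactors = FALSE))
}
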