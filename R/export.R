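# 32-bit helpers on doubles (R has no unsigned 32-bit integer type)
.xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# (a * 16777619) mod 2^32 without double-precision loss
.mul32 <- function(a) {
  p <- 16777619
  lo <- (a %% 65536) * p
  hi <- ((a %/% 65536) * p) %% 65536
  (lo + hi * 65536) %% 2^32
}

#' Hash a configuration for run manifests
#'
#' 32-bit FNV-1a over the deparsed object; stable across runs for the
#' same configuration, used to stamp every report table.
#'
#' @param x any R object (typically a run configuration list)
#' @return 8-character hex string
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger")),
             collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- .mul32(.xor32(h, b))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a data frame as TSV with `#`-prefixed metadata header
#'
#' @param df data frame
#' @param path output file
#' @param meta named character vector written as `# key: value` lines
#' @return `path`, invisibly
#' @export
write_tsv_report <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a distance matrix in PHYLIP square format
#'
#' @param d symmetric numeric matrix with population dimnames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_phylip <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  nm <- sprintf("%-10s", substr(rownames(d), 1, 10))
  for (i in seq_len(nrow(d)))
    writeLines(paste0(nm[i], paste(sprintf("%.6f", d[i, ]),
                                   collapse = "  ")), con)
  invisible(path)
}

#' Export a distance matrix as a NEXUS distances block
#'
#' Consumable by split-network software (e.g. for neighbor-net rendering).
#'
#' @param d symmetric numeric matrix with population dimnames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_nexus_dist <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", nrow(d)),
               "  TAXLABELS",
               paste0("    ", rownames(d)),
               "  ;", "END;", "", "BEGIN DISTANCES;",
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;", "  MATRIX"), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste0("    ", sprintf("%-10s", rownames(d)[i]), " ",
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
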