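test_that("PLINK bed/bim/fam round-trip is exact, including missing codes", {
  set.seed(42)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 10 * 100, replace = TRUE,
                     prob = c(0.4, 0.3, 0.25, 0.05)), 10, 100)
  x <- make_geno(g, chr = rep(1:2, each = 50))
  x$samples$sex <- rep(c("male", "female", "unknown"), length.out = 10)
  pre <- file.path(tempdir(), "rt")
  write_plink(x, pre)
  y <- read_plink(pre)
  expect_identical(y$geno, x$geno)
  expect_equal(y$map, x$map)
  expect_identical(y$samples$sample_id, x$samples$sample_id)
  expect_identical(y$samples$sex, x$samples$sex)
  # sample count not divisible by 4 exercises byte padding
  x5 <- x[1:5, ]
  write_plink(x5, pre)
  expect_identical(read_plink(pre)$geno, x5$geno)
})

test_that("bed decoding follows the PLINK 2-bit convention byte for byte", {
  # 2 samples x 3 SNPs, bytes crafted by hand:
  # SNP1: s1=11 (hom A2), s2=10 (het)      -> 0b1011 = 11
  # SNP2: s1=01 (missing), s2=00 (hom A1)  -> 0b0001 = 1
  # SNP3: s1=10 (het), s2=11 (hom A2)      -> 0b1110 = 14
  pre <- file.path(tempdir(), "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 11, 1, 14)), paste0(pre, ".bed"))
  writeLines(c("1\ts1\t0\t100\tA\tG", "1\ts2\t0\t200\tA\tG",
               "1\ts3\t0\t300\tA\tG"), paste0(pre, ".bim"))
  writeLines(c("F1\ti1\t0\t0\t1\t-9", "F1\ti2\t0\t0\t2\t-9"),
             paste0(pre, ".fam"))
  unlink(paste0(pre, ".samples.tsv"))
  x <- read_plink(pre)
  expect_identical(x$geno, matrix(c(2L, 1L, NA, 0L, 1L, 2L), 2, 3))
  # and writing missing codes produces 01 bit-pairs at those cells
  write_plink(x, pre, samples_tsv = FALSE)
  raw <- readBin(paste0(pre, ".bed"), "raw", 10)
  expect_identical(as.integer(raw[4:6]), c(11L, 1L, 14L))
})

test_that("malformed inputs raise distinct errors", {
  pre <- file.path(tempdir(), "bad")
  expect_error(read_plink(file.path(tempdir(), "absent")),
               class = "ovipop_missing_file")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 11)), paste0(pre, ".bed"))
  writeLines("1\ts1\t0\t100\tA\tG", paste0(pre, ".bim"))
  writeLines("F1\ti1\t0\t0\t1\t-9", paste0(pre, ".fam"))
  expect_error(read_plink(pre), class = "ovipop_bad_magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 11, 12)), paste0(pre, ".bed"))
  expect_error(read_plink(pre), class = "ovipop_dim_mismatch")
})

test_that("empty datasets write a header-only bed and empty bim", {
  x <- make_geno(matrix(integer(0), 3, 0))
  pre <- file.path(tempdir(), "empty")
  write_plink(x, pre)
  expect_identical(readBin(paste0(pre, ".bed"), "raw", 10),
                   as.raw(c(0x6c, 0x1b, 0x01)))
  expect_identical(file.size(paste0(pre, ".bim")), 0)
})

test_that("ped/map text datasets decode with A1 as the rarer allele", {
  pre <- file.path(tempdir(), "txt")
  writeLines(c("1\tm1\t0\t1000", "1\tm2\t0\t2000", "2\tm3\t0\t500"),
             paste0(pre, ".map"))
  writeLines(c("BRD\ta1\t0\t0\t1\t-9\tA A\tC C\tG T",
               "BRD\ta2\t0\t0\t2\t-9\tA G\t0 0\tT T",
               "BRD\ta3\t0\t0\t0\t-9\tG G\tC C\tT T"),
             paste0(pre, ".ped"))
  x <- read_ped(pre)
  # m1: A and G tie 3-3 -> alphabetical tie-break, A1 = A; codes count G
  expect_identical(x$map$a1[1], "A")
  expect_identical(x$map$a2[1], "G")
  expect_identical(x$geno[, 1], c(0L, 1L, 2L))
  # m2 monomorphic C: a1 recorded as "0"
  expect_identical(x$map$a1[2], "0")
  expect_identical(x$geno[, 2], c(2L, NA, 2L))
  # m3: G is rarer than T
  expect_identical(x$map$a1[3], "G")
  expect_identical(x$geno[, 3], c(1L, 2L, 2L))
  expect_identical(x$samples$breed, rep("BRD", 3))
})

test_that("merge keeps the SNP intersection and reconciles swapped alleles", {
  a <- make_geno(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 2, 3), breed = "AAA")
  a$map$snp_id <- c("s1", "s2", "s3")
  b <- make_geno(matrix(c(2L, 0L, 1L, 1L, 0L, 2L), 2, 3), breed = "BBB")
  b$map$snp_id <- c("s2", "s3", "s4")
  b$map$pos_bp <- a$map$pos_bp[2:3] |> c(4e5)  # align shared coordinates
  b$samples$sample_id <- c("x1", "x2")
  # b's s2 has swapped alleles
  b$map$a1[1] <- "G"; b$map$a2[1] <- "A"
  m <- merge_datasets(a, b)
  expect_setequal(m$map$snp_id, c("s2", "s3"))
  expect_identical(nrow(m$geno), 4L)
  # swapped-allele SNP recoded 2 - g for b's samples
  expect_identical(m$geno[3:4, m$map$snp_id == "s2"], c(0L, 2L))
  expect_identical(m$geno[3:4, m$map$snp_id == "s3"], c(1L, 1L))
  # symmetric in SNP content
  m2 <- merge_datasets(b, a)
  expect_setequal(m2$map$snp_id, m$map$snp_id)
  # self-merge under renamed samples: SNP set unchanged, samples doubled
  a2 <- a
  a2$samples$sample_id <- paste0("dup_", a$samples$sample_id)
  sm <- merge_datasets(a, a2)
  expect_identical(sm$map$snp_id, a$map$snp_id)
  expect_identical(nrow(sm$geno), 4L)
  expect_error(merge_datasets(a, a), "duplicate sample_ids")
  c0 <- a
  c0$map$snp_id <- c("z1", "z2", "z3")
  c0$samples$sample_id <- c("y1", "y2")
  expect_error(merge_datasets(a, c0), "zero overlapping")
})

test_that("QC removes SNPs before samples and re-evaluates to a fixpoint", {
  # SNP3 misses 2/10 samples (20% > 10%): removed first. Sample 2 misses
  # SNP1 and SNP3; after SNP3 goes, it still misses 1/4 (> 5%): removed.
  # Sample 7 missed only SNP3 and is fully observed afterwards: kept.
  g <- matrix(0L, 10, 5)
  g[2, c(1, 3)] <- NA
  g[7, 3] <- NA
  x <- make_geno(g)
  q <- qc_filter(x)
  rep <- attr(q, "qc_report")
  expect_identical(rep$removed_snp_missing, 1L)
  expect_identical(rep$removed_sample_missing, 1L)
  expect_identical(dim(q$geno), c(9L, 4L))
  expect_false("ind2" %in% q$samples$sample_id)
  expect_true("ind7" %in% q$samples$sample_id)
  # fully observed matrix is untouched
  x0 <- make_geno(matrix(1L, 3, 4))
  q0 <- qc_filter(x0)
  expect_identical(q0$geno, x0$geno)
  expect_identical(attr(q0, "qc_report")$removed_snp_missing, 0L)
  # non-autosomal SNP (chr 27 = X) removed when autosomes_only
  x27 <- make_geno(matrix(0L, 4, 3), chr = c(1L, 1L, 27L),
                   pos = c(100, 200, 100))
  q27 <- qc_filter(x27)
  expect_identical(ncol(q27$geno), 2L)
  expect_identical(attr(q27, "qc_report")$removed_nonautosomal, 1L)
})

test_that("QC is idempotent", {
  set.seed(7)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 30 * 80, replace = TRUE,
                     prob = c(0.35, 0.3, 0.25, 0.10)), 30, 80)
  x <- make_geno(g)
  q1 <- qc_filter(x)
  q2 <- qc_filter(q1)
  expect_identical(q2$geno, q1$geno)
  expect_identical(q2$map, q1$map)
  expect_identical(attr(q2, "qc_report")$removed_snp_missing, 0L)
  expect_identical(attr(q2, "qc_report")$removed_sample_missing, 0L)
})

test_that("QC errors instead of returning an empty dataset", {
  # every sample misses 3/40 SNPs (7.5% > 5%) but each SNP is missed by
  # at most 2/20 samples (10%, not above threshold): sample rule fires
  g <- matrix(0L, 20, 40)
  for (i in 1:20) g[i, (3 * (i - 1) + seq_len(3) - 1) %% 40 + 1] <- NA
  expect_error(qc_filter(make_geno(g)), "every sample")
  x <- make_geno(matrix(0L, 3, 2), chr = c(27L, 30L), pos = c(100, 100))
  expect_error(qc_filter(x), "every SNP")
})

test_that("LD pruning drops duplicated columns and spares independent SNPs", {
  set.seed(11)
  base <- matrix(sample(0:2, 40 * 6, replace = TRUE), 40, 6)
  base[, 4] <- base[, 3]  # r2 = 1 pair
  x <- make_geno(base)
  pr <- ld_prune(x, window_snps = 50, step_snps = 5, r2_threshold = 0.1)
  expect_true(xor("snp3" %in% pr$map$snp_id, "snp4" %in% pr$map$snp_id))
  # independent simulated SNPs survive a high threshold
  g <- matrix(rbinom(60 * 20, 2, 0.5), 60, 20)
  x2 <- make_geno(g)
  pr2 <- ld_prune(x2, r2_threshold = 0.6)
  expect_identical(ncol(pr2$geno), 20L)
  expect_error(ld_prune(x, window_snps = 3, step_snps = 5), "window")
})

test_that("windowed pruning matches the exhaustive greedy oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 35
    base <- rbinom(n, 2, 0.5)
    g <- sapply(1:6, function(j) {
      flip <- runif(n) < runif(1, 0, 0.6)
      ifelse(flip, rbinom(n, 2, 0.5), base)
    })
    x <- make_geno(g)
    pr <- ld_prune(x, window_snps = 50, step_snps = 5, r2_threshold = 0.1)
    keep <- oracle_prune_window(g, 0.1)
    expect_identical(match(pr$map$snp_id, x$map$snp_id), keep)
  }
})

test_that("no retained within-window pair exceeds the r2 threshold", {
  set.seed(3)
  n <- 50
  g <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  for (j in seq(2, 30, by = 3)) g[, j] <- g[, j - 1]  # heavy LD
  x <- make_geno(g, chr = rep(1:2, each = 15))
  pr <- ld_prune(x, window_snps = 10, step_snps = 2, r2_threshold = 0.2)
  for (ch in 1:2) {
    idx <- which(pr$map$chr == ch)
    orig <- match(pr$map$snp_id[idx], x$map$snp_id)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (orig[b] - orig[a] >= 9) next  # never surely co-windowed
        r2 <- ovipop:::dosage_r2(pr$geno[, idx[a]], pr$geno[, idx[b]])
        if (!is.na(r2)) expect_lte(r2, 0.2)
      }
    }
  }
})
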