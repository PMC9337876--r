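test_that("the minimum-SNP threshold reproduces its closed form", {
  # alpha/(n_s*n_i) = 5e-6; ln(5e-6)/ln(0.5) = 17.6 -> 17
  expect_identical(min_snp_threshold(0.05, 1000, 10, 0.5), 17L)
  # boundary clamp: tiny search space still demands at least one SNP
  expect_identical(min_snp_threshold(0.9999, 1, 1, 0.9), 1L)
  expect_error(min_snp_threshold(0.05, 1000, 10, 0), "het")
  expect_error(min_snp_threshold(0.05, 1000, 10, 1), "het")
})

test_that("an individual heterozygous everywhere has no runs", {
  x <- make_geno(matrix(1L, 1, 300), pos = seq(4e4, by = 4e4,
                                               length.out = 300))
  seg <- detect_roh(x, roh_params(l_min_snps = 20L))
  expect_identical(nrow(seg), 0L)
})

test_that("a planted homozygous tract is found with exact endpoints", {
  pos <- seq(4e4, by = 4e4, length.out = 100)  # 40 kb spacing
  g <- rep(1L, 100)
  g[20:80] <- 0L  # span 2.4 Mb, 61 SNPs
  x <- make_geno(matrix(g, 1), pos = pos)
  params <- roh_params(l_min_snps = 50L)
  seg <- detect_roh(x, params)
  expect_identical(nrow(seg), 1L)
  expect_equal(seg$start_bp, pos[20])
  expect_equal(seg$end_bp, pos[80])
  expect_identical(seg$n_snps, 61L)
  expect_identical(seg$n_het, 0L)
  expect_identical(seg$length_class, "2-4Mb")
  # agrees with the brute-force oracle
  oro <- oracle_roh(g, pos, params)
  expect_identical(oro$start_idx, 20L)
  expect_identical(oro$end_idx, 80L)
})

test_that("an oversized gap splits a tract and pieces are re-tested", {
  pos <- seq(4e4, by = 4e4, length.out = 100)
  g <- rep(1L, 100)
  g[10:90] <- 0L
  pos[36:100] <- pos[36:100] + 2.6e5  # gap 35->36 becomes 300 kb
  x <- make_geno(matrix(g, 1), pos = pos)
  params <- roh_params(l_min_snps = 50L)
  seg <- detect_roh(x, params)
  # left piece (10..35, 1 Mb) dies on length and SNP count; right survives
  expect_identical(nrow(seg), 1L)
  expect_equal(seg$start_bp, pos[36])
  expect_equal(seg$end_bp, pos[90])
  oro <- oracle_roh(g, pos, params)
  expect_identical(oro$start_idx, 36L)
  expect_identical(oro$end_idx, 90L)
})

test_that("F_ROH partitions by length class and sums exactly", {
  # covered genome: one chromosome spanning 1e8 bp
  map <- data.frame(snp_id = c("a", "b"), chr = 1L, pos_bp = c(1, 1e8),
                    a1 = "A", a2 = "G")
  seg <- data.frame(sample_id = "i1", chr = 1L,
                    start_bp = c(1e6, 5e7), end_bp = c(1e6 + 3e6 - 1,
                                                       5e7 + 1e7 - 1),
                    length_bp = c(3e6, 1e7),
                    length_class = c("2-4Mb", "8-16Mb"),
                    stringsAsFactors = FALSE)
  f <- froh(seg, map)
  expect_equal(f$froh_total, 0.13)
  expect_equal(f$froh_2_4, 0.03)
  expect_equal(f$froh_4_8, 0)
  expect_equal(f$froh_8_16, 0.10)
  expect_equal(f$froh_gt16, 0)
  # no segments -> all zero
  f0 <- froh(seg[0, ], map)
  expect_true(all(unlist(f0) == 0))
  # a run covering the whole covered genome gives F_ROH = 1
  seg1 <- data.frame(sample_id = "i1", chr = 1L, start_bp = 1, end_bp = 1e8,
                     length_bp = 1e8, length_class = ">16Mb")
  expect_equal(froh(seg1, map)$froh_total, 1)
})

test_that("breed means of F_ROH have textbook two-point statistics", {
  ftab <- data.frame(sample_id = c("a", "b", "c", "d"),
                     breed = c("X", "X", "Y", "Y"),
                     froh_total = c(0.02, 0.04, 0.05, 0.05))
  bf <- breed_froh(ftab)
  expect_equal(bf$froh_total_mean[bf$breed == "X"], 0.03)
  expect_equal(bf$froh_total_se[bf$breed == "X"], 0.01)
  expect_equal(bf$froh_total_se[bf$breed == "Y"], 0)
})

test_that("class F_ROH values are additive and scanning order is immaterial", {
  cfg <- sim_config(n_chromosomes = 4L, chromosome_length_bp = 50e6,
                    n_snps_per_chromosome = 2000L,
                    ne_schedule = list(c(4L, 60L)), n_samples = 15,
                    seed = 9)
  sim <- plant_inbred_offspring(simulate_population(cfg), "full-sib", 5)
  x <- sim$data
  params <- roh_params(x)
  seg <- detect_roh(x, params)
  expect_gt(nrow(seg), 0L)
  ft <- froh_table(seg, x)
  class_cols <- setdiff(grep("^froh_", names(ft), value = TRUE),
                        "froh_total")
  expect_equal(rowSums(ft[class_cols]), ft$froh_total,
               ignore_attr = TRUE, tolerance = 1e-12)
  # relabel chromosomes in reverse order: same segments modulo labels
  x2 <- x
  relab <- 5L - x2$map$chr
  ord <- order(relab, x2$map$pos_bp)
  x2 <- genotypes(x2$geno[, ord],
                  data.frame(snp_id = x2$map$snp_id[ord], chr = relab[ord],
                             pos_bp = x2$map$pos_bp[ord],
                             a1 = "A", a2 = "G"),
                  x2$samples)
  seg2 <- detect_roh(x2, params)
  key <- function(s) {
    k <- s[order(s$sample_id, s$start_bp, s$n_snps), ]
    k[c("sample_id", "start_bp", "end_bp", "n_snps", "n_het")]
  }
  s1 <- seg[order(seg$sample_id, seg$start_bp, seg$n_snps),
            c("sample_id", "start_bp", "end_bp", "n_snps", "n_het")]
  rownames(s1) <- NULL
  s2 <- key(seg2)
  rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("segments respect every criterion in the parameters", {
  fx <- random_roh_fixture(400, seed = 77)
  x <- make_geno(matrix(fx$g, 1), pos = fx$pos)
  seg <- detect_roh(x, fx$params)
  if (nrow(seg) > 0) {
    expect_true(all(seg$length_bp >= fx$params$min_length_bp))
    expect_true(all(seg$n_snps >= fx$params$l_min_snps))
    expect_true(all(seg$n_snps / seg$length_bp >=
                      fx$params$min_density_snp_per_bp))
    cls <- findInterval(seg$length_bp, fx$params$class_edges_bp)
    expect_true(all(seg$n_het <= fx$params$het_allow[cls]))
    expect_true(all(seg$n_missing <= fx$params$miss_allow[cls]))
  }
  expect_error(detect_roh(x, fx$params, sample_ids = "ghost"), "unknown")
})
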