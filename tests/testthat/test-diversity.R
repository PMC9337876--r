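# Expected values below were computed by hand/with independent arithmetic
# on the printed toy genotypes before the implementation was run.

test_that("Ho, He and F_IS match the hand-computed toy", {
  g <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, 0L, 1L), c(0L, NA, 1L))
  x <- make_geno(g, breed = "TOY")
  d <- breed_diversity(x, "TOY")
  expect_equal(d$ho_mean, 0.458333333, tolerance = 1e-8)
  expect_equal(d$ho_se, 0.079785592, tolerance = 1e-7)
  expect_equal(d$he_mean, 0.546825397, tolerance = 1e-8)
  expect_equal(d$he_se, 0.012320774, tolerance = 1e-7)
  expect_equal(d$fis_mean, 0.164614448, tolerance = 1e-8)
  expect_equal(d$fis_se, 0.145447829, tolerance = 1e-7)
  expect_error(breed_diversity(x, "NOPE"), "breed not present")
})

test_that("an all-heterozygous breed has Ho = 1 and negative F_IS", {
  x <- make_geno(matrix(1L, 5, 20), breed = "HET")
  d <- breed_diversity(x, "HET")
  expect_equal(d$ho_mean, 1)
  expect_lt(d$fis_mean, 0)
})

test_that("Weir-Cockerham components and F_ST match the hand-worked toy", {
  w <- ovipop:::.wc_components(n1 = c(4, 4, 4), n2 = c(4, 4, 4),
                               p1 = c(0.25, 0, 0.5), p2 = c(0.75, 1, 0.5),
                               h1 = c(0.5, 0, 0.5), h2 = c(0.5, 0, 0.5))
  expect_equal(w$a, c(0.104166667, 0.5, -0.041666667), tolerance = 1e-7)
  expect_equal(w$b, c(-0.041666667, 0, 0.041666667), tolerance = 1e-7)
  expect_equal(w$c, c(0.25, 0, 0.25), tolerance = 1e-7)
  # same toy through the user-facing estimator: ratio of sums
  g <- rbind(c(0L, 0L, 1L), c(0L, 0L, 1L), c(1L, 0L, 0L), c(1L, 0L, 2L),
             c(2L, 2L, 1L), c(2L, 2L, 1L), c(1L, 2L, 2L), c(1L, 2L, 0L))
  x <- make_geno(g, breed = rep(c("P1", "P2"), each = 4))
  expect_equal(pairwise_fst(x, "P1", "P2"), 0.529411765, tolerance = 1e-7)
})

test_that("F_ST and Nei D are near zero for samples of one population", {
  cfg <- sim_config(n_chromosomes = 4L, chromosome_length_bp = 60e6,
                    n_snps_per_chromosome = 1250L,
                    ne_schedule = list(c(5L, 200L)), seed = 20)
  sim <- simulate_split_pair(cfg, t_split = 0L, n_per_pop = 50L)
  f <- pairwise_fst(sim$data, "POPA", "POPB")
  expect_lt(abs(f), 0.005)
  # Nei (1972) D has no sample-size correction, so two finite samples of
  # one population sit near D ~ mean(2pq)/(2n J) rather than exactly 0
  nd <- nei_distance(allele_freqs(sim$data))
  expect_lt(nd["POPA", "POPB"], 0.01)
})

test_that("pairwise F_ST grows with divergence time", {
  rho <- sapply(1:3, function(rep) {
    est <- sapply(c(10L, 50L, 100L), function(t) {
      cfg <- sim_config(n_chromosomes = 2L, n_snps_per_chromosome = 750L,
                        ne_schedule = list(c(100L, 100L)),
                        seed = 1000 * rep + t)
      sim <- simulate_split_pair(cfg, t_split = t, n_per_pop = 30L)
      pairwise_fst(sim$data, "POPA", "POPB")
    })
    cor(est, c(10, 50, 100), method = "spearman")
  })
  expect_identical(unname(rho), rep(1, 3))
})

test_that("mean F_ST averages the off-diagonal entries", {
  m <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  m["X", "Y"] <- m["Y", "X"] <- 0.01
  m["X", "Z"] <- m["Z", "X"] <- 0.03
  m["Y", "Z"] <- m["Z", "Y"] <- 0.05
  expect_equal(mean_fst(m, "X"), 0.02)
  expect_equal(unname(mean_fst(matrix(0, 2, 2,
                                      dimnames = list(c("A", "B"),
                                                      c("A", "B"))))),
               c(0, 0))
  expect_error(mean_fst(m[1, 1, drop = FALSE]), "single breed")
  # reconstructing a published mean-F_ST column entry from its printed
  # pairwise values: Dalmatian Pramenka vs the 14 other panel breeds
  dps <- c(TAR = 0.033, NMS = 0.042, RIS = 0.016, PIS = 0.015, NVE = 0.037,
           MER = 0.033, LPS = 0.003, LEC = 0.023, LAC = 0.041, KIS = 0.029,
           ISS = 0.040, DRS = 0.026, CIS = 0.031, ALT = 0.034)
  k <- length(dps) + 1
  m2 <- matrix(0, k, k, dimnames = list(c("DPS", names(dps)),
                                        c("DPS", names(dps))))
  m2["DPS", -1] <- dps
  m2[-1, "DPS"] <- dps
  expect_equal(mean_fst(m2, "DPS"), 0.029, tolerance = 0.015)
})

test_that("Nei distance reproduces the two-locus closed form", {
  f <- cbind(p1 = c(1, 0.5), p2 = c(0, 0.5))
  d <- nei_distance(f)
  expect_equal(d["p1", "p2"], log(3), tolerance = 1e-9)
  expect_equal(diag(d), c(p1 = 0, p2 = 0))
  # identical frequency vectors give zero
  expect_equal(nei_distance(cbind(a = c(0.3, 0.7), b = c(0.3, 0.7)))["a", "b"],
               0)
  # symmetric and invariant to locus order
  set.seed(8)
  f2 <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  d2 <- nei_distance(f2)
  expect_equal(d2, t(d2))
  expect_equal(nei_distance(f2[sample(20), ]), d2)
  # drift-only alternative is also a valid distance on this input
  expect_gt(nei_distance(f, method = "reynolds")["p1", "p2"], 0)
  expect_error(nei_distance(cbind(a = c(NA, NA), b = c(0.3, 0.7))),
               "undefined frequencies")
})

test_that("the small-sample He correction never falls below plugin 2pq", {
  set.seed(5)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 12 * 200, replace = TRUE), 12, 200)
  he <- ovipop:::.he_by_snp(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  plugin <- 2 * p * (1 - p)
  ok <- !is.na(he)
  expect_true(all(he[ok] >= plugin[ok] - 1e-12))
})

test_that("PCA separates simulated diverged populations on PC1", {
  cfg <- sim_config(n_chromosomes = 2L, n_snps_per_chromosome = 750L,
                    ne_schedule = list(c(12L, 100L)), seed = 31)
  sim <- simulate_split_pair(cfg, t_split = 12L, n_per_pop = 30L)
  pc <- snp_pca(sim$data)
  sil <- silhouette_1d(pc$coords[, 1], sim$data$samples$breed)
  expect_gt(sil, 0)
  expect_true(all(diff(pc$varfrac) <= 1e-8))
  expect_lte(sum(pc$varfrac), 100 + 1e-8)
})

test_that("duplicating every sample leaves PCA structure unchanged", {
  x <- sim_genotypes_example(4)
  dup <- genotypes(rbind(x$geno, x$geno), x$map,
                   data.frame(sample_id = c(x$samples$sample_id,
                                            paste0("d_",
                                                   x$samples$sample_id)),
                              breed = rep(x$samples$breed, 2)))
  p1 <- snp_pca(x, k = 4)
  p2 <- snp_pca(dup, k = 4)
  n <- nrow(x$geno)
  expect_equal(p2$coords[seq_len(n), ], p2$coords[n + seq_len(n), ],
               ignore_attr = TRUE)
  expect_equal(p2$varfrac, p1$varfrac, tolerance = 1e-8)
  expect_error(snp_pca(make_geno(matrix(2L, 5, 3))), "polymorphic")
})
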