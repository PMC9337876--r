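`%||%` <- function(a, b) if (is.null(a)) b else a

# quick genotypes builder: g is samples x SNPs; positions strictly
# increasing within each chromosome
make_geno <- function(g, chr = NULL, pos = NULL, breed = "TST",
                      a1 = "A", a2 = "G") {
  g <- as.matrix(g)
  m <- ncol(g)
  if (is.null(chr)) chr <- rep(1L, m)
  if (is.null(pos)) pos <- stats::ave(seq_len(m), chr, FUN = seq_along) * 1e5
  genotypes(g,
            map = data.frame(snp_id = sprintf("snp%d", seq_len(m)), chr = chr,
                             pos_bp = pos, a1 = rep_len(a1, m),
                             a2 = rep_len(a2, m), stringsAsFactors = FALSE),
            samples = data.frame(sample_id = paste0("ind", seq_len(nrow(g))),
                                 breed = rep_len(breed, nrow(g)),
                                 stringsAsFactors = FALSE))
}

# three-breed PLINK fixture for pipeline-level tests
make_pipeline_fixture <- function(dir, seed = 5) {
  cfg <- sim_config(n_chromosomes = 4L, chromosome_length_bp = 60e6,
                    n_snps_per_chromosome = 300L,
                    ne_schedule = list(c(25L, 80L)), n_samples = 60,
                    missing_rate = 0.01, seed = seed)
  sim <- simulate_population(cfg)
  x <- sim$data
  x$samples$breed <- rep(c("AAA", "BBB", "CCC"), each = 20)
  write_plink(x, file.path(dir, "fx"))
  file.path(dir, "fx")
}

# mean silhouette width of a 1-d embedding under two labels
silhouette_1d <- function(v, lab) {
  labs <- unique(lab)
  stopifnot(length(labs) == 2L)
  s <- vapply(seq_along(v), function(i) {
    d <- abs(v - v[i])
    a <- mean(d[lab == lab[i]][-match(i, which(lab == lab[i]))])
    b <- mean(d[lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
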