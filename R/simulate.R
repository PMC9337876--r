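# Counter-based seed splitting: every stochastic entry point reseeds the R
# RNG with a sub-seed derived from (master seed, purpose tag), so the same
# master seed reproduces each scenario independently of call order.
derive_seed <- function(seed, tag) {
  m <- 2147483647  # 2^31 - 1
  h <- seed %% m
  for (b in utf8ToInt(tag)) h <- (h * 69069 + b) %% m
  as.integer(h)
}

#' Configuration for the Wright-Fisher simulator
#'
#' Describes a simulated SNP-array dataset: genome layout (sheep-like
#' defaults: 26 autosomes of 100 Mb at 1 cM/Mb), founder allele-frequency
#' law (uniform, emulating array ascertainment of common standing
#' variation), a diploid population-size schedule, the number of sampled
#' individuals, and a missing-call rate. There is no mutation: all
#' variation is standing variation present in the founders.
#'
#' @param n_chromosomes number of autosomes (default 26)
#' @param chromosome_length_bp length of every chromosome (default 100 Mb)
#' @param n_snps_per_chromosome markers per chromosome (default 1500)
#' @param recomb_rate_cM_per_Mb uniform genetic map rate (default 1.0)
#' @param founder_freq_range range of the uniform founder allele-frequency
#'   law (default 0.05-0.95)
#' @param ne_schedule list of `c(generations, N)` spans, executed in
#'   order; e.g. `list(c(50, 200), c(10, 20))` runs 50 generations at
#'   diploid size 200 then a 10-generation bottleneck at 20
#' @param n_samples individuals genotyped from the final generation
#' @param missing_rate per-call missing probability, in \[0, 0.05\]
#' @param seed master seed (mandatory)
#' @return a `sim_config` object
#' @export
sim_config <- function(n_chromosomes = 26L, chromosome_length_bp = 100e6,
                       n_snps_per_chromosome = 1500L,
                       recomb_rate_cM_per_Mb = 1.0,
                       founder_freq_range = c(0.05, 0.95),
                       ne_schedule = list(c(20L, 100L)),
                       n_samples = 50L, missing_rate = 0,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_chromosomes >= 1, chromosome_length_bp >= 2,
            n_snps_per_chromosome >= 2, recomb_rate_cM_per_Mb > 0,
            length(founder_freq_range) == 2,
            founder_freq_range[1] > 0, founder_freq_range[2] < 1,
            missing_rate >= 0, missing_rate <= 0.05, n_samples >= 2)
  ne_schedule <- lapply(ne_schedule, function(s) {
    s <- as.integer(unlist(s))
    if (length(s) != 2L || s[1] < 1L || s[2] < 2L)
      stop("ne_schedule entries must be c(generations >= 1, N >= 2)")
    s
  })
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 n_snps_per_chromosome = as.integer(n_snps_per_chromosome),
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 founder_freq_range = as.numeric(founder_freq_range),
                 ne_schedule = ne_schedule,
                 n_samples = as.integer(n_samples),
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  tot <- sum(vapply(x$ne_schedule, `[`, integer(1), 1L))
  cat(sprintf(paste0("sim_config: %d chromosomes x %.0f Mb, %d SNPs/chr, ",
                     "%.2g cM/Mb\n"),
              x$n_chromosomes, x$chromosome_length_bp / 1e6,
              x$n_snps_per_chromosome, x$recomb_rate_cM_per_Mb))
  cat(sprintf("  schedule: %s (%d generations); sample %d; seed %d\n",
              paste(vapply(x$ne_schedule, function(s)
                sprintf("%dx N=%d", s[1], s[2]), character(1)),
                collapse = ", "),
              tot, x$n_samples, x$seed))
  invisible(x)
}

.schedule_vector <- function(cfg)
  unlist(lapply(cfg$ne_schedule, function(s) rep(s[2], s[1])))

# genome layout shared by the C++ kernels
.sim_layout <- function(cfg, map) {
  morgans_per_bp <- cfg$recomb_rate_cM_per_Mb * 1e-8
  chr_start <- c(0L, cumsum(tabulate(map$chr, nbins = cfg$n_chromosomes)))
  list(chr_start = as.integer(chr_start),
       gpos = map$pos_bp * morgans_per_bp,
       chr_len = rep(cfg$chromosome_length_bp * morgans_per_bp,
                     cfg$n_chromosomes))
}

.sim_map <- function(cfg) {
  pos <- lapply(seq_len(cfg$n_chromosomes), function(ch)
    sort(sample.int(cfg$chromosome_length_bp, cfg$n_snps_per_chromosome)))
  data.frame(
    snp_id = paste0("c", rep(seq_len(cfg$n_chromosomes),
                             each = cfg$n_snps_per_chromosome),
                    "_s", seq_len(cfg$n_snps_per_chromosome)),
    chr = rep(seq_len(cfg$n_chromosomes),
              each = cfg$n_snps_per_chromosome),
    pos_bp = as.numeric(unlist(pos)), a1 = "A", a2 = "G",
    stringsAsFactors = FALSE)
}

.founder_hap <- function(cfg) {
  L <- cfg$n_chromosomes * cfg$n_snps_per_chromosome
  n0 <- .schedule_vector(cfg)[1]
  p <- stats::runif(L, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  h <- matrix(as.raw(stats::rbinom(2L * n0 * L, 1L, rep(p, each = 2L * n0))),
              nrow = 2L * n0)
  h
}

# draw genotypes for chosen individuals (1-based) from a haplotype matrix
.hap_genotypes <- function(hap, individuals, missing_rate) {
  h <- matrix(as.integer(hap), nrow = nrow(hap))
  g <- h[2L * individuals - 1L, , drop = FALSE] +
    h[2L * individuals, , drop = FALSE]
  if (missing_rate > 0) {
    drop <- stats::runif(length(g)) < missing_rate
    g[drop] <- NA_integer_
  }
  g
}

.as_wf_sim <- function(geno, map, samples, hap, truth, cfg, scenario) {
  structure(list(
    data = genotypes(geno, map, samples),
    hap = hap, truth = truth, config = cfg, scenario = scenario),
    class = "wf_sim")
}

#' @export
print.wf_sim <- function(x, ...) {
  cat("Wright-Fisher simulation (", x$scenario$kind, ")\n", sep = "")
  print(x$data)
  if (nrow(x$truth$individuals) > 0)
    cat(sprintf("  flagged individuals with pedigree F: %d\n",
                sum(x$truth$individuals$flagged)))
  if (nrow(x$truth$pairs) > 0)
    cat(sprintf("  population pairs with expected F_ST: %d\n",
                nrow(x$truth$pairs)))
  invisible(x)
}

#' Simulate a single population
#'
#' Discrete-generation Wright-Fisher reproduction with random distinct
#' parent pairs, Poisson-count crossovers placed uniformly along each
#' chromosome, and no mutation. Genotypes are emitted for a random sample
#' of the final generation. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config]
#' @return a `wf_sim` object: `$data` is a [genotypes] object (breed code
#'   `"SIM"`), `$truth` holds founder and final allele frequencies plus
#'   (empty) pedigree/pair truth tables, `$hap` the final haplotype pool
#' @export
simulate_population <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "population"))
  map <- .sim_map(cfg)
  layout <- .sim_layout(cfg, map)
  hap0 <- .founder_hap(cfg)
  founder_freq <- colMeans(matrix(as.integer(hap0), nrow = nrow(hap0)))
  hap <- wf_evolve(hap0, layout$chr_start, layout$gpos, layout$chr_len,
                   .schedule_vector(cfg))
  nfinal <- nrow(hap) / 2L
  if (cfg$n_samples > nfinal)
    stop("n_samples exceeds final population size")
  pick <- sort(sample.int(nfinal, cfg$n_samples))
  g <- .hap_genotypes(hap, pick, cfg$missing_rate)
  samples <- data.frame(sample_id = sprintf("SIM_%03d", seq_len(nrow(g))),
                        breed = "SIM", stringsAsFactors = FALSE)
  truth <- list(
    individuals = data.frame(sample_id = character(), pedigree_f = numeric(),
                             flagged = logical(), stringsAsFactors = FALSE),
    pairs = data.frame(pop_a = character(), pop_b = character(),
                       t_split = integer(), n_diploid = integer(),
                       expected_fst = numeric(), stringsAsFactors = FALSE),
    founder_freq = founder_freq,
    final_freq = colMeans(matrix(as.integer(hap), nrow = nrow(hap))))
  .as_wf_sim(g, map, samples, hap, truth, cfg,
             scenario = list(kind = "population"))
}

#' Simulate an ancestral population split into two drifting descendants
#'
#' One ancestral population is evolved through `cfg$ne_schedule`, then
#' duplicated into two isolated descendants that each drift `t_split`
#' further generations at the schedule's final size `N`. Under pure
#' drift the expected differentiation is
#' `F_ST = 1 - (1 - 1/(2N))^t_split`, recorded in the truth table.
#'
#' @param cfg a [sim_config]; its `n_samples` is ignored in favour of
#'   `n_per_pop`
#' @param t_split generations of isolation (0 = one panmictic population
#'   sampled twice); must not exceed the generations in `cfg$ne_schedule`
#' @param n_per_pop individuals sampled from each descendant
#' @param final_cohort census size of the last generation of each
#'   descendant (default `max(N, 4 * n_per_pop)`). The parents of that
#'   cohort are still the `N`-sized pool, so each of the `t_split` rounds
#'   contributes drift `1/(2N)` and the expectation
#'   `F_ST = 1 - (1 - 1/(2N))^t_split` is unchanged; genotyping a cohort
#'   much larger than the sample emulates field studies (census >> n) and
#'   keeps the estimators' binomial-sampling correction appropriate
#' @return a `wf_sim`; breeds are `"POPA"` and `"POPB"`
#' @export
simulate_split_pair <- function(cfg, t_split, n_per_pop,
                                final_cohort = NULL) {
  t_split <- as.integer(t_split)
  total <- sum(vapply(cfg$ne_schedule, `[`, integer(1), 1L))
  if (t_split < 0L) stop("t_split must be >= 0")
  if (t_split > total)
    stop("t_split (", t_split, ") exceeds the simulated history (",
         total, " generations)")
  set.seed(derive_seed(cfg$seed, paste0("split_", t_split)))
  map <- .sim_map(cfg)
  layout <- .sim_layout(cfg, map)
  hap0 <- .founder_hap(cfg)
  anc <- wf_evolve(hap0, layout$chr_start, layout$gpos, layout$chr_len,
                   .schedule_vector(cfg))
  n_final <- nrow(anc) / 2L
  n_last <- utils::tail(.schedule_vector(cfg), 1L)
  if (t_split == 0L) {
    if (2L * n_per_pop > n_final)
      stop("2 * n_per_pop exceeds the population size")
    pick <- sample.int(n_final, 2L * n_per_pop)
    ga <- .hap_genotypes(anc, sort(pick[seq_len(n_per_pop)]),
                         cfg$missing_rate)
    gb <- .hap_genotypes(anc, sort(pick[n_per_pop + seq_len(n_per_pop)]),
                         cfg$missing_rate)
    hap_a <- anc; hap_b <- anc
  } else {
    if (is.null(final_cohort))
      final_cohort <- max(n_last, 4L * n_per_pop)
    # t_split full drift rounds at N, then one census-expansion round whose
    # own drift (~1/(2*final_cohort)) cancels, to first order, the
    # finite-population part of the estimators' sampling correction
    sched <- c(rep(n_last, t_split), as.integer(final_cohort))
    hap_a <- wf_evolve(anc, layout$chr_start, layout$gpos, layout$chr_len,
                       sched)
    hap_b <- wf_evolve(anc, layout$chr_start, layout$gpos, layout$chr_len,
                       sched)
    if (n_per_pop > final_cohort)
      stop("n_per_pop exceeds the final cohort size")
    ga <- .hap_genotypes(hap_a, sort(sample.int(final_cohort, n_per_pop)),
                         cfg$missing_rate)
    gb <- .hap_genotypes(hap_b, sort(sample.int(final_cohort, n_per_pop)),
                         cfg$missing_rate)
  }
  g <- rbind(ga, gb)
  samples <- data.frame(
    sample_id = c(sprintf("POPA_%03d", seq_len(n_per_pop)),
                  sprintf("POPB_%03d", seq_len(n_per_pop))),
    breed = rep(c("POPA", "POPB"), each = n_per_pop),
    stringsAsFactors = FALSE)
  truth <- list(
    individuals = data.frame(sample_id = character(), pedigree_f = numeric(),
                             flagged = logical(), stringsAsFactors = FALSE),
    pairs = data.frame(pop_a = "POPA", pop_b = "POPB", t_split = t_split,
                       n_diploid = n_last,
                       expected_fst = 1 - (1 - 1 / (2 * n_last))^t_split,
                       stringsAsFactors = FALSE),
    founder_freq = NULL, final_freq = NULL)
  sim <- .as_wf_sim(g, map, samples, hap_a, truth, cfg,
                    scenario = list(kind = "split_pair", t_split = t_split,
                                    n_per_pop = as.integer(n_per_pop),
                                    final_cohort =
                                      if (t_split > 0L)
                                        as.integer(final_cohort)
                                      else NULL))
  sim$hap_b <- hap_b
  sim
}

#' Append offspring of close-relative matings
#'
#' Plants `count` matings of the requested type into a simulated
#' population and appends their offspring, flagged with pedigree
#' inbreeding F = 0.25: `"parent-offspring"` mates an individual A with
#' its own child (by an unrelated B); `"full-sib"` mates two full sibs.
#' The offspring genomes carry identity-by-descent tracts generated by
#' the same recombination process as the rest of the simulation, so ROH
#' detection can be validated against pedigree expectation.
#'
#' @param sim a `wf_sim` from [simulate_population()]
#' @param type `"parent-offspring"` or `"full-sib"`
#' @param count number of matings (each uses a fresh pair of parents;
#'   `2 * count` must not exceed the final population size)
#' @return the extended `wf_sim`; offspring have breed `"INB"` and truth
#'   rows with `pedigree_f = 0.25`, existing samples keep `pedigree_f = 0`
#' @export
plant_inbred_offspring <- function(sim, type = c("parent-offspring",
                                                 "full-sib"),
                                   count = 1L) {
  type <- match.arg(type)
  cfg <- sim$config
  set.seed(derive_seed(cfg$seed, paste0("inbred_", type, "_", count)))
  nind <- nrow(sim$hap) / 2L
  if (2L * count > nind)
    stop("count too large: ", count, " matings need ", 2L * count,
         " parents but the population has ", nind)
  layout <- .sim_layout(cfg, sim$data$map)
  parents <- matrix(sample.int(nind, 2L * count), ncol = 2L)
  if (type == "parent-offspring") {
    child <- wf_offspring(sim$hap, parents - 1L, layout$chr_start,
                          layout$gpos, layout$chr_len)
    pool <- rbind(sim$hap, child)
    off <- wf_offspring(pool, cbind(parents[, 1], nind + seq_len(count)) - 1L,
                        layout$chr_start, layout$gpos, layout$chr_len)
  } else {
    sibs <- wf_offspring(sim$hap, rbind(parents, parents) - 1L,
                         layout$chr_start, layout$gpos, layout$chr_len)
    pool <- rbind(sim$hap, sibs)
    off <- wf_offspring(pool,
                        cbind(nind + seq_len(count),
                              nind + count + seq_len(count)) - 1L,
                        layout$chr_start, layout$gpos, layout$chr_len)
  }
  g_off <- .hap_genotypes(off, seq_len(count), cfg$missing_rate)
  tag <- if (type == "parent-offspring") "PO" else "FS"
  ids <- sprintf("INB_%s_%03d", tag, seq_len(count))
  old_truth_ids <- sim$truth$individuals$sample_id
  base_ids <- setdiff(sim$data$samples$sample_id, old_truth_ids)
  sim$truth$individuals <- rbind(
    sim$truth$individuals,
    data.frame(sample_id = base_ids, pedigree_f = 0, flagged = FALSE,
               stringsAsFactors = FALSE),
    data.frame(sample_id = ids, pedigree_f = 0.25, flagged = TRUE,
               stringsAsFactors = FALSE))
  sim$data <- structure(list(
    geno = rbind(sim$data$geno, g_off),
    map = sim$data$map,
    samples = rbind(sim$data$samples,
                    data.frame(sample_id = ids, breed = "INB",
                               sex = "unknown", group = "unknown",
                               stringsAsFactors = FALSE))),
    class = "genotypes")
  sim$scenario <- list(kind = "inbred", type = type,
                       count = as.integer(count))
  sim
}

#' Write a simulated fixture to disk
#'
#' Emits the PLINK triplet, a truth TSV (one row per flagged individual
#' and per population pair), and a YAML file holding the full
#' configuration and scenario so the fixture can be regenerated
#' byte-identically with [regenerate_fixture()].
#'
#' @param sim a `wf_sim`
#' @param prefix output path prefix
#' @return `prefix`, invisibly
#' @export
write_fixture <- function(sim, prefix) {
  write_plink(sim$data, prefix)
  tr <- sim$truth
  rows <- list()
  ind <- tr$individuals[tr$individuals$flagged, , drop = FALSE]
  if (nrow(ind) > 0)
    rows[[1]] <- data.frame(record = "pedigree_f", id = ind$sample_id,
                            partner = "", value = ind$pedigree_f,
                            t_split = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(tr$pairs) > 0)
    rows[[2]] <- data.frame(record = "expected_fst", id = tr$pairs$pop_a,
                            partner = tr$pairs$pop_b,
                            value = tr$pairs$expected_fst,
                            t_split = tr$pairs$t_split,
                            stringsAsFactors = FALSE)
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record = character(), id = character(), partner = character(),
               value = numeric(), t_split = integer(),
               stringsAsFactors = FALSE)
  utils::write.table(truth, paste0(prefix, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$ne_schedule <- lapply(cfg$ne_schedule, as.integer)
  yaml::write_yaml(list(config = cfg, scenario = sim$scenario),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Regenerate a fixture from its stored YAML
#'
#' @param yaml_path path to the `.yaml` written by [write_fixture()]
#' @return the regenerated `wf_sim` (identical to the original for the
#'   stored seed)
#' @export
regenerate_fixture <- function(yaml_path) {
  spec <- yaml::read_yaml(yaml_path)
  cfg <- do.call(sim_config, spec$config)
  sc <- spec$scenario
  switch(sc$kind,
         population = simulate_population(cfg),
         split_pair = simulate_split_pair(cfg, sc$t_split, sc$n_per_pop,
                                          sc$final_cohort),
         inbred = plant_inbred_offspring(simulate_population(cfg),
                                         sc$type, sc$count),
         stop("unknown scenario kind: ", sc$kind))
}

#' Small simulated genotype set for examples
#'
#' @param seed master seed
#' @return a [genotypes] object (2 chromosomes, 120 SNPs, 30 samples)
#' @export
sim_genotypes_example <- function(seed = 1L) {
  cfg <- sim_config(n_chromosomes = 2L, chromosome_length_bp = 50e6,
                    n_snps_per_chromosome = 60L,
                    ne_schedule = list(c(5L, 60L)), n_samples = 30L,
                    seed = seed)
  simulate_population(cfg)$data
}
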