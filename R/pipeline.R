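.run_config_schema <- list(
  input_prefix = "character", out_dir = "character", seed = "integer",
  breeds = "character",
  qc = list(max_snp_missing = "numeric", max_sample_missing = "numeric",
            autosomes_only = "logical", autosomes = "integer"),
  prune = list(window_snps = "integer", step_snps = "integer",
               r2_threshold = "numeric"),
  roh = list(alpha = "numeric", max_gap_bp = "numeric",
             min_density_snp_per_bp = "numeric", min_length_bp = "numeric",
             het = "numeric", l_min_snps = "integer"),
  ne = list(c_edges = "numeric", rate_cM_per_Mb = "numeric",
            max_pairs_per_bin = "integer", min_pairs = "integer",
            min_breed_n = "integer"),
  pca_k = "integer", fst_method = "character", distance_method = "character")

.check_keys <- function(x, schema, where = "config") {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown) > 0L)
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(x)) {
    if (is.list(schema[[k]]) && !is.null(x[[k]]))
      .check_keys(x[[k]], schema[[k]], paste0(where, "$", k))
  }
  invisible(TRUE)
}

#' Build or load a pipeline run configuration
#'
#' The configuration drives [run_characterization()]. Unknown keys are
#' rejected so that typos cannot silently fall back to defaults. A path
#' to a YAML file may be given instead of arguments.
#'
#' @param input_prefix PLINK prefix of the input dataset
#' @param out_dir output directory for [write_report_bundle()]
#' @param seed master seed for subsampling steps
#' @param breeds optional breed registry: analyses are restricted to and
#'   validated against these codes
#' @param qc,prune,roh,ne optional named lists overriding defaults of
#'   [qc_filter()], [ld_prune()], [roh_params()] and [binned_r2()]
#' @param pca_k number of principal components to keep
#' @param fst_method `"wc"` or `"hudson"`
#' @param distance_method `"nei"` or `"reynolds"`
#' @param yaml path to a YAML file holding these keys; other arguments
#'   are then ignored
#' @return a `run_config` object
#' @export
run_config <- function(input_prefix = NULL, out_dir = NULL, seed = 1L,
                       breeds = NULL, qc = list(), prune = list(),
                       roh = list(), ne = list(), pca_k = 10L,
                       fst_method = "wc", distance_method = "nei",
                       yaml = NULL) {
  if (!is.null(yaml)) {
    raw <- yaml::read_yaml(yaml)
    .check_keys(raw, .run_config_schema)
    cfg <- do.call(run_config, raw)
    return(cfg)
  }
  cfg <- list(input_prefix = input_prefix, out_dir = out_dir,
              seed = as.integer(seed), breeds = breeds,
              qc = qc, prune = prune, roh = roh, ne = ne,
              pca_k = as.integer(pca_k), fst_method = fst_method,
              distance_method = distance_method)
  .check_keys(cfg, .run_config_schema)
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full characterization pipeline
#'
#' Executes, in order: QC, per-breed diversity, pairwise F_ST with breed
#' means, genetic distances, PCA, LD pruning, ROH detection, F_ROH by
#' length class, and LD-based Ne trajectories per breed. Any stage error
#' aborts the run with the stage named. The result is deterministic for a
#' fixed configuration and input.
#'
#' @param cfg a [run_config]; alternatively pass `data` directly
#' @param data optional [genotypes] object (skips reading
#'   `cfg$input_prefix`)
#' @return a `report_bundle`: list with `diversity` (Ho/He/F_IS table
#'   joined with mean F_ST, F_ROH > 2 Mb and current Ne per breed),
#'   `fst`, `distances`, `pca`, `froh_individual`, `froh_class`,
#'   `roh_segments`, `ne_trajectories`, `qc_report`, `pruned_n` and
#'   `manifest`
#' @export
run_characterization <- function(cfg, data = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(data)) {
    if (is.null(cfg$input_prefix)) stop("config lacks input_prefix")
    data <- .stage("read", read_plink(cfg$input_prefix))
  }
  if (!is.null(cfg$breeds)) {
    bad <- setdiff(data$samples$breed, cfg$breeds)
    if (length(bad) > 0L)
      stop("stage [read] failed: breeds outside the registry: ",
           paste(unique(bad), collapse = ", "))
  }
  qc <- .stage("qc", do.call(qc_filter, c(list(data), cfg$qc)))
  qc_rep <- attr(qc, "qc_report")
  tb <- table(qc$samples$breed)
  breeds <- names(tb)[tb >= 2L]
  if (!is.null(cfg$breeds)) breeds <- intersect(cfg$breeds, breeds)

  div <- .stage("diversity", diversity_table(qc, breeds))
  fst <- .stage("fst", if (length(breeds) >= 2L)
    fst_matrix(qc, breeds, method = cfg$fst_method) else NULL)
  dist <- .stage("distances",
                 nei_distance(allele_freqs(qc, breeds),
                              method = cfg$distance_method))
  pca <- .stage("pca", snp_pca(qc, k = cfg$pca_k))
  pruned <- .stage("prune", do.call(ld_prune, c(list(qc), cfg$prune)))
  params <- .stage("roh", do.call(roh_params, c(list(qc), cfg$roh)))
  segments <- .stage("roh", detect_roh(qc, params))
  ftab <- .stage("froh", froh_table(segments, qc))
  fclass <- .stage("froh", breed_froh(ftab))

  ne_args <- cfg$ne
  min_breed_n <- ne_args$min_breed_n %||% 10L
  ne_args$min_breed_n <- NULL
  traj <- .stage("ne", {
    out <- list()
    for (b in breeds) {
      if (tb[[b]] < min_breed_n) next
      bins <- tryCatch(
        do.call(binned_r2, c(list(qc, breed = b, seed = cfg$seed), ne_args)),
        error = function(e) NULL)
      tr <- if (is.null(bins)) NULL else
        tryCatch(ne_trajectory(bins), error = function(e) NULL)
      if (!is.null(tr)) out[[b]] <- tr
    }
    out
  })

  current_ne <- vapply(breeds, function(b)
    if (!is.null(traj[[b]])) attr(traj[[b]], "current_ne") else NA_real_,
    numeric(1))
  fmean <- fclass[match(breeds, fclass$breed), ]
  summary_tab <- cbind(div,
                       mfst = if (!is.null(fst))
                         unname(fst$mfst[div$breed]) else NA_real_,
                       froh_mean = fmean$froh_total_mean,
                       froh_se = fmean$froh_total_se,
                       current_ne = unname(current_ne))
  manifest <- list(package_version = as.character(
    utils::packageVersion("ovipop")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = config_hash(unclass(cfg)),
    note = "floating point results may differ across platforms")
  structure(list(diversity = summary_tab, fst = fst, distances = dist,
                 pca = pca, froh_individual = ftab, froh_class = fclass,
                 roh_segments = segments, ne_trajectories = traj,
                 qc_report = qc_rep,
                 pruned_n = ncol(pruned$geno), manifest = manifest,
                 config = cfg),
            class = "report_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.report_bundle <- function(x, ...) {
  cat("Characterization report (config ", x$manifest$config_hash, ")\n",
      sep = "")
  cat(sprintf("  %d breeds; %d SNPs after QC; %d after pruning\n",
              nrow(x$diversity), x$qc_report$n_snps_out, x$pruned_n))
  print(x$diversity, digits = 3)
  invisible(x)
}

#' Write all report tables of a run
#'
#' Emits TSV tables (diversity, F_ST matrix with mean-F_ST column, F_ROH
#' by class, Ne trajectories, PCA coordinates, ROH segments, QC report)
#' plus the distance matrix in PHYLIP and NEXUS formats. Every table
#' carries the configuration hash in its `#` header; re-running the same
#' configuration on the same input reproduces the files byte-identically.
#'
#' @param bundle a `report_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- c(config_hash = bundle$manifest$config_hash,
            seed = as.character(bundle$manifest$seed))
  p <- function(f) file.path(dir, f)
  write_tsv_report(bundle$diversity, p("diversity.tsv"), meta)
  if (!is.null(bundle$fst)) {
    m <- bundle$fst$fst
    df <- data.frame(breed = rownames(m), as.data.frame(round(m, 6)),
                     mfst = round(bundle$fst$mfst, 6))
    write_tsv_report(df, p("fst_matrix.tsv"), meta)
  }
  write_tsv_report(bundle$froh_class, p("froh_by_class.tsv"), meta)
  write_tsv_report(bundle$froh_individual, p("froh_individual.tsv"), meta)
  write_tsv_report(bundle$roh_segments, p("roh_segments.tsv"), meta)
  if (length(bundle$ne_trajectories) > 0) {
    tr <- do.call(rbind, lapply(names(bundle$ne_trajectories), function(b) {
      d <- as.data.frame(bundle$ne_trajectories[[b]])
      cbind(breed = b, d)
    }))
    write_tsv_report(tr, p("ne_trajectory.tsv"), meta)
  }
  coords <- data.frame(sample_id = rownames(bundle$pca$coords),
                       breed = bundle$pca$samples$breed,
                       round(bundle$pca$coords, 6))
  write_tsv_report(coords, p("pca_coords.tsv"),
                   c(meta, varfrac_percent =
                       paste(sprintf("%.3f", bundle$pca$varfrac),
                             collapse = ",")))
  write_phylip(bundle$distances, p("distances.phy"))
  write_nexus_dist(bundle$distances, p("distances.nex"))
  write_qc_report(bundle$qc_report, p("qc_report.tsv"))
  manifest <- data.frame(key = names(bundle$manifest),
                         value = vapply(bundle$manifest, as.character,
                                        character(1)))
  write_tsv_report(manifest, p("manifest.tsv"))
  invisible(dir)
}
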