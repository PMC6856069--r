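# End-to-end orchestration: config, input validation, the full
# preprocess -> state calling -> set algebra -> topography -> enrichment run
# with report files and a structured run log.

#' Pipeline configuration
#'
#' All study thresholds, overridable: detection-p QC cutoff 0.01, M-value
#' state cutoffs +/-2, FDR 0.05, top-K 10,000, desert coverage minimum 50,
#' bootstrap replicates 200.
#'
#' @param detection_p_threshold sample QC cutoff on mean detection p.
#' @param hyper_min,hypo_max M-value state-calling cutoffs.
#' @param fdr FDR threshold for differential calls.
#' @param top_k probes used for heatmap ordering.
#' @param min_probes desert-band coverage guard.
#' @param bootstrap arm-vs-genome bootstrap replicates.
#' @param epsilon beta->M clamp.
#' @param clip track export |M| display range.
#' @param heatmap_probes cap on the probe dendrogram size in reports.
#' @param diff_groups optional length-2 character vector: run a two-group
#'   differential comparison (A vs B) as part of the pipeline.
#' @param exclude_arms arms excluded from arm ratios.
#' @param seed integer seed for the bootstrap stage.
#' @param out_dir report output directory (`NULL` = no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection_p_threshold = 0.01,
                            hyper_min = 2, hypo_max = -2,
                            fdr = 0.05, top_k = 10000, min_probes = 50,
                            bootstrap = 200, epsilon = 1e-6,
                            clip = c(1.9, 7), heatmap_probes = 2000,
                            diff_groups = NULL,
                            exclude_arms = ACROCENTRIC_P_ARMS,
                            seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(detection_p_threshold > 0, detection_p_threshold <= 1,
            hyper_min > hypo_max, fdr > 0, fdr < 1,
            top_k >= 1, min_probes >= 0, bootstrap >= 2,
            epsilon > 0, epsilon < 0.5, length(clip) == 2, clip[1] < clip[2])
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys are rejected; missing keys fall back to defaults, so a
#' config round-trips through serialization.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop2("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
}

#' Validate a dataset bundle before running the pipeline
#'
#' Checks manifest/matrix/sheet consistency (ids, beta range, duplicate
#' samples), genome tiling and group sizes. Reports violations; never
#' raises.
#'
#' @param manifest manifest data.frame.
#' @param beta beta-value matrix (probes x samples).
#' @param sheet sample sheet.
#' @param genome optional [genome_table()].
#' @return character vector of violations (length 0 when clean).
#' @export
validate_inputs <- function(manifest, beta, sheet, genome = NULL) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  miss <- setdiff(c("probe_id", "chromosome", "position"), names(manifest))
  if (length(miss)) add(paste("manifest missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(manifest$probe_id)) add("duplicated probe_id in manifest")
  if (any(manifest$position < 1, na.rm = TRUE)) add("manifest positions < 1")
  if (anyDuplicated(sheet$sample_id)) add("duplicated sample_id in sheet")
  orphan <- setdiff(colnames(beta), sheet$sample_id)
  if (length(orphan))
    add(paste("matrix column(s) absent from sample sheet:", paste(orphan, collapse = ", ")))
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) add("beta values outside [0, 1]")
  unknown_probe <- setdiff(rownames(beta), manifest$probe_id)
  if (length(unknown_probe))
    add(paste(length(unknown_probe), "matrix probe(s) absent from manifest"))
  if (!is.null(genome)) {
    chk <- tryCatch({
      genome_table(genome$chromosomes, genome$centromeres, genome$cytobands)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(chk)) add(paste("genome:", chk))
    badchr <- setdiff(unique(manifest$chromosome), genome$chromosomes$chrom)
    if (length(badchr))
      add(paste("manifest chromosome(s) not in genome:", paste(badchr, collapse = ", ")))
  }
  tab <- table(sheet$group[sheet$sample_id %in% colnames(beta)])
  small <- names(tab)[tab < 2]
  if (length(small)) add(paste("group(s) with < 2 samples:", paste(small, collapse = ", ")))
  v
}

#' Run the full methylation topography pipeline
#'
#' QC -> sex-probe removal -> platform harmonization -> quantile
#' normalization -> M-values -> per-group state calls -> common/unique set
#' algebra and specificity table -> arm ratios, genome-wide region tests,
#' bootstrap arm-vs-genome tests, desert bands -> track export -> optional
#' two-group differential comparison and over-representation analysis.
#' Stages run in the order of the source study's workflow; every threshold
#' comes from the config and is recorded in the run log.
#'
#' @param manifest manifest data.frame (sex probes still present is fine).
#' @param beta beta matrix, probes x samples.
#' @param detection_p detection p-value matrix (same shape); `NULL` skips QC.
#' @param sheet sample sheet.
#' @param genome a [genome_table()].
#' @param config a [pipeline_config()].
#' @param gene_sets optional named list of gene sets for ORA on the common
#'   hypo/hyper gene lists.
#' @return list of class `methtopo_report`: qc, universe, m, state_calls,
#'   collection, common, specificity, venn, arm_ratios, region_ratios,
#'   arm_tests, deserts, heatmap, diff (optional), ora (optional), log.
#' @export
run_pipeline <- function(manifest, beta, detection_p = NULL, sheet, genome,
                         config = pipeline_config(), gene_sets = NULL) {
  log <- character(0)
  note <- function(...) {
    log <<- c(log, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("stage '", name, "' failed: ", conditionMessage(e)))
  }
  note("methtopo run; seed=", config$seed,
       "; thresholds: detp<", config$detection_p_threshold,
       ", M in [", config$hypo_max, ",", config$hyper_min,
       "], FDR<", config$fdr, ", top_k=", config$top_k,
       ", min_probes=", config$min_probes, ", B=", config$bootstrap)
  note("background adjustment: not applicable post-beta (intensity-level); skipped")

  # --- preprocess -----------------------------------------------------
  qc <- NULL
  keep_samples <- colnames(beta)
  if (!is.null(detection_p)) {
    qc <- stage("qc", qc_filter_samples(detection_p, config$detection_p_threshold))
    keep_samples <- intersect(colnames(beta), qc$kept)
    note("qc: kept ", length(keep_samples), "/", ncol(beta), " samples")
  }
  manifest <- stage("filter", drop_sex_probes(manifest))
  universe <- stage("harmonize", harmonize_platforms(split_platforms(manifest)))
  note("universe: ", length(universe), " overlapping probes after filtering")
  manifest <- manifest[match(universe, manifest$probe_id), , drop = FALSE]
  beta <- beta[universe, keep_samples, drop = FALSE]
  sheet <- sheet[sheet$sample_id %in% keep_samples, , drop = FALSE]
  beta <- stage("normalize", quantile_normalize(beta))
  m <- stage("convert", beta_to_m(beta, config$epsilon))

  # --- state calling over the full universe, per group ----------------
  groups <- unique(sheet$group)
  state_calls <- stage("states", {
    out <- lapply(groups, function(g)
      call_states(group_mean_m(m, sheet, g), config$hyper_min, config$hypo_max))
    names(out) <- groups
    out
  })
  for (g in groups)
    note("states[", g, "]: hyper=", sum(state_calls[[g]]$state == "hyper"),
         " hypo=", sum(state_calls[[g]]$state == "hypo"))

  # --- set algebra ----------------------------------------------------
  collection <- stage("sets", make_state_sets(state_calls))
  common <- list(hyper = common_probes(collection, "hyper"),
                 hypo = common_probes(collection, "hypo"))
  note("common: hyper=", length(common$hyper), " hypo=", length(common$hypo))
  specificity <- stage("sets", specificity_table(collection))
  venn <- stage("sets", lapply(stats::setNames(STATES, STATES), function(st)
    venn_counts(collection, st)))

  # --- topography -----------------------------------------------------
  if (is.null(manifest$arm)) manifest <- stage("topography", assign_arms(manifest, genome))
  armtab <- stage("topography",
                  arm_ratios(common, manifest, genome, config$exclude_arms))
  region_ratios <- stage("topography", genomewide_region_ratios(armtab))
  arm_tests <- stage("topography",
                     arm_vs_genome_test(common, manifest, genome,
                                        b = config$bootstrap, seed = config$seed,
                                        exclude_arms = config$exclude_arms))
  deserts <- stage("topography",
                   desert_bands(common, manifest, genome, config$min_probes))
  note("deserts: ", sum(deserts$desert), " band(s) flagged")

  # --- heatmap ordering on the most variable probes -------------------
  grand_mean <- rowMeans(vapply(state_calls, function(s) s$mean_m,
                                numeric(nrow(manifest))))
  heatmap <- stage("heatmap", {
    v <- apply(m, 1, stats::var)
    top <- names(sort(v, decreasing = TRUE))[seq_len(min(config$heatmap_probes, nrow(m)))]
    hierarchical_order(m[top, , drop = FALSE])
  })

  # --- optional two-group differential comparison ---------------------
  diff <- NULL
  if (!is.null(config$diff_groups)) {
    diff <- stage("diffmeth", {
      res <- diff_methylation(m, sheet, config$diff_groups[1],
                              config$diff_groups[2], fdr = config$fdr)
      list(result = res,
           top = top_k_probes(res, min(config$top_k, nrow(res))),
           region_counts = region_direction_counts(res, manifest))
    })
    note("diff ", config$diff_groups[1], " vs ", config$diff_groups[2], ": ",
         sum(diff$result$significant), " probes at FDR<", config$fdr)
  }

  # --- optional enrichment --------------------------------------------
  ora_res <- NULL
  if (!is.null(gene_sets)) {
    ora_res <- stage("enrichment", {
      uni <- probes_to_genes(manifest$probe_id, manifest)
      lapply(stats::setNames(STATES, STATES), function(st)
        lapply(stats::setNames(REGIONS, REGIONS), function(rg)
          ora(probes_to_genes(common[[st]], manifest, rg), gene_sets, uni)))
    })
  }

  report <- structure(
    list(qc = qc, universe = universe, manifest = manifest, genome = genome, m = m,
         state_calls = state_calls, collection = collection, common = common,
         specificity = specificity, venn = venn, arm_ratios = armtab,
         region_ratios = region_ratios, arm_tests = arm_tests,
         deserts = deserts, mean_m = stats::setNames(grand_mean, manifest$probe_id),
         heatmap = heatmap, diff = diff, ora = ora_res,
         config = config, log = log),
    class = "methtopo_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.methtopo_report <- function(x, ...) {
  cat(paste(x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write pipeline report files
#'
#' Emits the specificity and Venn tables, arm-ratio table, desert report,
#' differential table (if run), ORA tables (if run), bedGraph/BED tracks,
#' the resolved config and the run log, all as plain text.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(report$qc)) wt(report$qc$report, "qc_report.tsv")
  writeLines(report$universe, file.path(dir, "universe_probes.txt"))
  write_specificity_table(report$specificity, file.path(dir, "specificity_table.tsv"))
  for (st in names(report$venn))
    write_venn_counts(report$venn[[st]], file.path(dir, paste0("venn_", st, ".tsv")))
  wt(report$arm_ratios, "arm_ratios.tsv")
  wt(report$region_ratios$ratios, "region_ratios.tsv")
  wt(report$region_ratios$tests, "region_ratio_tests.tsv")
  wt(report$arm_tests, "arm_vs_genome_tests.tsv")
  wt(report$deserts, "desert_report.tsv")
  if (!is.null(report$diff)) {
    wt(report$diff$result, "differential_methylation.tsv")
    wt(report$diff$region_counts, "differential_region_counts.tsv")
  }
  if (!is.null(report$ora))
    for (st in names(report$ora)) for (rg in names(report$ora[[st]]))
      wt(report$ora[[st]][[rg]], paste0("ora_", st, "_", rg, ".tsv"))
  export_tracks(report$common, report$mean_m, report$manifest,
                genome = report$genome, dir = file.path(dir, "tracks"),
                clip = report$config$clip, deserts = report$deserts)
  write_pipeline_config(report$config, file.path(dir, "config.yaml"))
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
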