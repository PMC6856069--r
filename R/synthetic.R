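# Synthetic array-data generator: genome, manifest, group beta matrices with
# planted functional and topographic structure, plus a machine-readable
# truth record for parameter-recovery testing.
#
# Model: each probe gets a baseline beta mode (unmethylated ~0.1,
# intermediate ~0.5, methylated ~0.85) with region-dependent mixture
# weights (promoters mostly unmethylated, gene bodies / enhancers mostly
# methylated -- the CpG-island asymmetry of real arrays). Group-specific
# effects add a per-region Delta-M (promoter -3, body/enhancer +3) to a
# random fraction of the intermediate-baseline probes of each group, so the
# shift alone decides the called state. Designated desert cytobands carry
# annotation but are forced to the neutral baseline with no effects.
# Per-sample noise is Gaussian on the M scale; betas come from the inverse
# logit2 transform.

#' Synthetic study specification
#'
#' Defaults size the scenario used throughout the test-suite: a 6-chromosome
#' genome (one acrocentric), 20,000 probes, six tumor-type groups of 8
#' samples, |Delta M| = 3 planted effects and M-scale noise sd 0.5.
#'
#' @param n_probes number of probes.
#' @param groups group (tumor type) labels.
#' @param samples_per_group samples per group.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param acrocentric chromosomes whose centromere sits at the start (no p
#'   arm probe capacity).
#' @param band_size approximate cytoband width (bp).
#' @param desert_bands character vector `"<chrom>:<band>"` of designated
#'   effect-free, neutral-baseline bands.
#' @param region_probs probability of each primary annotation
#'   (promoter / gene_body / enhancer / none).
#' @param overlap_prob chance a probe carries a second region annotation.
#' @param beta_modes baseline beta of the unmethylated / intermediate /
#'   methylated modes.
#' @param mode_weights list per region of (low, mid, high) mixture weights.
#' @param arm_enrichment list of `list(arm=, region=, multiplier=)` entries
#'   scaling the methylated-mode weight on specific arms.
#' @param effect_delta_m named per-region M shift planted in affected probes.
#' @param affected_fraction fraction of a region's intermediate-baseline
#'   probes affected per group.
#' @param control_groups groups receiving no planted effects (e.g. a
#'   wild-type arm).
#' @param noise_sd Gaussian noise sd on the M scale.
#' @param platform_overlap probability a probe is on both platforms (the
#'   remainder splits evenly between 450K-only and EPIC-only).
#' @param n_genes size of the gene-symbol pool probes map into.
#' @param detection_p_max upper bound of baseline detection p-values.
#' @param bad_sample_fraction fraction of samples given elevated detection
#'   p-values (QC failures); 0 by default, as every study sample passed QC.
#' @param bad_p_range detection p range for failing samples.
#' @return list of class `truth_spec`.
#' @export
synth_spec <- function(
    n_probes = 20000,
    groups = c("aml", "astro", "odg", "breast", "chol", "snuc"),
    samples_per_group = 8,
    chrom_lengths = stats::setNames(seq(100e6, 50e6, by = -10e6),
                                    paste0("chr", 1:6)),
    acrocentric = "chr6",
    band_size = 5e6,
    desert_bands = c("chr2:q3", "chr3:p2", "chr5:q2"),
    region_probs = c(promoter = 0.28, gene_body = 0.40,
                     enhancer = 0.17, none = 0.15),
    overlap_prob = 0.12,
    beta_modes = c(low = 0.1, mid = 0.5, high = 0.85),
    mode_weights = list(promoter = c(0.60, 0.15, 0.25),
                        gene_body = c(0.20, 0.15, 0.65),
                        enhancer = c(0.20, 0.15, 0.65),
                        none = c(0.35, 0.30, 0.35)),
    arm_enrichment = list(list(arm = "chr1q", region = "gene_body",
                               multiplier = 1.35)),
    effect_delta_m = c(promoter = -3, gene_body = 3, enhancer = 3),
    affected_fraction = 0.3,
    control_groups = character(0),
    noise_sd = 0.5,
    platform_overlap = 0.8,
    n_genes = 3000,
    detection_p_max = 0.005,
    bad_sample_fraction = 0,
    bad_p_range = c(0.2, 0.6)) {
  spec <- as.list(environment())
  stopifnot(abs(sum(region_probs) - 1) < 1e-8,
            all(vapply(mode_weights, function(w) abs(sum(w) - 1) < 1e-8, logical(1))),
            overlap_prob >= 0, overlap_prob <= 1,
            platform_overlap >= 0, platform_overlap <= 1,
            noise_sd >= 0)
  structure(spec, class = "truth_spec")
}

#' Build the synthetic genome table
#'
#' Chromosomes with centromere gaps and a tiling cytoband set; acrocentric
#' chromosomes get a start-anchored centromere and hence no p-arm probe
#' capacity. Fully deterministic given the spec.
#'
#' @param spec a [synth_spec()].
#' @return a [genome_table()].
#' @export
make_genome <- function(spec) {
  chroms <- data.frame(chrom = names(spec$chrom_lengths),
                       length = unname(spec$chrom_lengths),
                       stringsAsFactors = FALSE)
  cen <- lapply(seq_len(nrow(chroms)), function(i) {
    L <- chroms$length[i]
    if (chroms$chrom[i] %in% spec$acrocentric)
      c(0, 4e6)
    else
      c(round(0.45 * L), round(0.55 * L))
  })
  centromeres <- data.frame(chrom = chroms$chrom,
                            start = vapply(cen, `[`, numeric(1), 1),
                            end = vapply(cen, `[`, numeric(1), 2),
                            stringsAsFactors = FALSE)
  bands <- list()
  for (i in seq_len(nrow(chroms))) {
    ch <- chroms$chrom[i]; L <- chroms$length[i]
    cs <- centromeres$start[i]; ce <- centromeres$end[i]
    tile <- function(from, to, prefix, reverse_names) {
      n <- max(1L, round((to - from) / spec$band_size))
      cuts <- round(seq(from, to, length.out = n + 1))
      nums <- if (reverse_names) rev(seq_len(n)) else seq_len(n)
      data.frame(chrom = ch, start = cuts[-length(cuts)], end = cuts[-1],
                 band = paste0(prefix, nums),
                 stain = rep_len(c("gneg", "gpos50"), n),
                 stringsAsFactors = FALSE)
    }
    part <- list()
    # p bands numbered outward from the centromere (p1 adjacent to it)
    if (cs > 0) part <- c(part, list(tile(0, cs, "p", reverse_names = TRUE)))
    part <- c(part, list(data.frame(chrom = ch, start = cs, end = ce,
                                    band = "cen", stain = "acen",
                                    stringsAsFactors = FALSE)))
    if (ce < L) part <- c(part, list(tile(ce, L, "q", reverse_names = FALSE)))
    bands[[i]] <- do.call(rbind, part)
  }
  genome_table(chroms, centromeres, do.call(rbind, bands))
}

#' Build the synthetic probe manifest
#'
#' Probes are placed uniformly outside centromere gaps, annotated with
#' regions (with the declared multi-membership probability), gene symbols,
#' platform flags and a baseline beta mode drawn from region-dependent
#' mixture weights (with arm-enrichment multipliers applied to the
#' methylated mode); designated desert-band probes are forced to the
#' intermediate mode.
#'
#' @param genome a [make_genome()] result.
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @return list: `manifest` (arm/band-assigned, with extra columns
#'   `baseline_class`, `desert`) and `baseline_m` (named per-probe baseline
#'   M-value).
#' @export
make_manifest <- function(genome, spec, seed = 1) {
  set.seed(seed)
  n <- spec$n_probes
  chroms <- genome$chromosomes
  cen <- genome$centromeres
  usable <- chroms$length - (cen$end - cen$start)
  ci <- sample.int(nrow(chroms), n, replace = TRUE, prob = usable / sum(usable))
  u <- floor(stats::runif(n, 0, usable[ci]))
  # skip the centromere gap: positions past its start shift beyond its end
  pos0 <- ifelse(u < cen$start[ci], u, u + (cen$end[ci] - cen$start[ci]))
  manifest <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(n)),
    chromosome = chroms$chrom[ci],
    position = as.integer(pos0 + 1),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  primary <- sample(names(spec$region_probs), n, replace = TRUE,
                    prob = spec$region_probs)
  for (rg in REGIONS) manifest[[rg]] <- primary == rg
  second <- stats::runif(n) < spec$overlap_prob & primary != "none"
  for (i in which(second)) {
    extra <- sample(setdiff(REGIONS, primary[i]), 1)
    manifest[[extra]][i] <- TRUE
  }
  manifest$genes <- paste0("G", sprintf("%04d", sample.int(spec$n_genes, n, replace = TRUE)))

  plat <- sample(c("both", "only450k", "onlyepic"), n, replace = TRUE,
                 prob = c(spec$platform_overlap,
                          (1 - spec$platform_overlap) / 2,
                          (1 - spec$platform_overlap) / 2))
  manifest$platform_450k <- plat != "onlyepic"
  manifest$platform_epic <- plat != "only450k"

  manifest <- assign_arms(manifest, genome)
  manifest$desert <- paste(manifest$chromosome, manifest$band, sep = ":") %in%
    spec$desert_bands

  # baseline mode: average the mixture weights of the probe's regions,
  # apply arm-enrichment multipliers to the methylated mode, renormalize
  w <- matrix(0, n, 3)
  nreg <- rowSums(as.matrix(manifest[REGIONS]))
  for (rg in REGIONS)
    w[manifest[[rg]], ] <- w[manifest[[rg]], ] +
      matrix(spec$mode_weights[[rg]], sum(manifest[[rg]]), 3, byrow = TRUE)
  w[nreg == 0, ] <- matrix(spec$mode_weights$none, sum(nreg == 0), 3, byrow = TRUE)
  w[nreg > 1, ] <- w[nreg > 1, , drop = FALSE] / nreg[nreg > 1]
  for (en in spec$arm_enrichment) {
    sel <- !is.na(manifest$arm) & manifest$arm == en$arm & manifest[[en$region]]
    if (any(sel)) {
      hi <- pmin(w[sel, 3] * en$multiplier, 0.95)
      scale <- (1 - hi) / (w[sel, 1] + w[sel, 2])
      w[sel, 1] <- w[sel, 1] * scale
      w[sel, 2] <- w[sel, 2] * scale
      w[sel, 3] <- hi
    }
  }
  r <- stats::runif(n)
  cls <- ifelse(r < w[, 1], "low", ifelse(r < w[, 1] + w[, 2], "mid", "high"))
  cls[manifest$desert] <- "mid"
  manifest$baseline_class <- cls
  mode_m <- beta_to_m(spec$beta_modes)
  baseline_m <- stats::setNames(unname(mode_m[cls]), manifest$probe_id)
  list(manifest = manifest, baseline_m = baseline_m)
}

#' Simulate beta matrices, detection p-values and the truth record
#'
#' Plants group-specific per-region Delta-M effects on a random fraction of
#' intermediate-baseline, non-desert probes of each (non-control) group,
#' adds Gaussian M-scale noise per sample, and converts to beta. The truth
#' record carries the expected mean M and the implied planted state per
#' probe and group.
#'
#' @param manifest_bundle a [make_manifest()] result.
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @return list: `beta` and `detection_p` (probes x samples matrices),
#'   `sheet` (sample sheet), `truth` (list: `expected_m` and `state`
#'   matrices probes x groups, plus the per-probe `manifest` columns).
#' @export
simulate_matrices <- function(manifest_bundle, spec, seed = 1) {
  set.seed(seed + 1L)
  manifest <- manifest_bundle$manifest
  baseline <- manifest_bundle$baseline_m
  n <- nrow(manifest)
  groups <- spec$groups

  delta <- matrix(0, n, length(groups), dimnames = list(manifest$probe_id, groups))
  eligible_base <- manifest$baseline_class == "mid" & !manifest$desert
  for (g in setdiff(groups, spec$control_groups)) {
    for (rg in names(spec$effect_delta_m)) {
      cand <- which(eligible_base & manifest[[rg]])
      hit <- cand[stats::runif(length(cand)) < spec$affected_fraction]
      delta[hit, g] <- delta[hit, g] + spec$effect_delta_m[[rg]]
    }
  }
  expected_m <- matrix(baseline, n, length(groups),
                       dimnames = dimnames(delta)) + delta
  state <- matrix(ifelse(expected_m >= 2, "hyper",
                         ifelse(expected_m <= -2, "hypo", "none")),
                  n, length(groups), dimnames = dimnames(delta))

  k <- spec$samples_per_group
  sheet <- data.frame(
    sample_id = paste0(rep(groups, each = k), "_", sprintf("%02d", seq_len(k))),
    group = rep(groups, each = k),
    platform = rep_len(c("A450K", "EPIC"), length(groups) * k),
    stringsAsFactors = FALSE)

  m <- expected_m[, sheet$group, drop = FALSE] +
    matrix(stats::rnorm(n * nrow(sheet), 0, spec$noise_sd), n, nrow(sheet))
  colnames(m) <- sheet$sample_id
  beta <- m_to_beta(m)

  detp <- matrix(stats::runif(n * nrow(sheet), 0, spec$detection_p_max),
                 n, nrow(sheet), dimnames = dimnames(beta))
  n_bad <- round(spec$bad_sample_fraction * nrow(sheet))
  if (n_bad > 0) {
    bad <- sample.int(nrow(sheet), n_bad)
    detp[, bad] <- matrix(stats::runif(n * n_bad, spec$bad_p_range[1],
                                       spec$bad_p_range[2]), n, n_bad)
  }
  list(beta = beta, detection_p = detp, sheet = sheet,
       truth = list(expected_m = expected_m, state = state,
                    delta = delta, manifest = manifest))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: genome, manifest and matrices from one spec and one
#' seed; the same (spec, seed) pair always reproduces the identical dataset.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @return list: spec, genome, manifest, baseline_m, beta, detection_p,
#'   sheet, truth.
#' @export
simulate_dataset <- function(spec = synth_spec(), seed = 1) {
  genome <- make_genome(spec)
  mb <- make_manifest(genome, spec, seed)
  sim <- simulate_matrices(mb, spec, seed)
  c(list(spec = spec, genome = genome, manifest = mb$manifest,
         baseline_m = mb$baseline_m), sim)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the same dialects the package readers consume: manifest, beta and
#' detection-p matrices, sample sheet and truth state table as TSV, plus
#' gap-style centromere and cytoband tables.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(dataset$manifest, file.path(dir, "manifest.tsv"))
  write_matrix(dataset$beta, file.path(dir, "beta.tsv"))
  write_matrix(dataset$detection_p, file.path(dir, "detection_p.tsv"))
  write_sample_sheet(dataset$sheet, file.path(dir, "sample_sheet.tsv"))
  cen <- dataset$genome$centromeres
  utils::write.table(data.frame(cen$chrom, cen$start, cen$end, "centromere"),
                     file.path(dir, "gap.txt"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$genome$cytobands, file.path(dir, "cytoband.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  st <- dataset$truth$state
  utils::write.table(data.frame(probe_id = rownames(st), st, check.names = FALSE),
                     file.path(dir, "truth_states.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Sensitivity and specificity of recovered state calls against the truth
#'
#' Pools probe x group decisions: for each state, sensitivity is the
#' fraction of truth-state entries called as that state, specificity the
#' fraction of non-truth-state entries not so called.
#'
#' @param calls_by_group named list of [call_states()] data.frames.
#' @param truth_state truth state matrix (probes x groups) from the
#'   generator.
#' @return data.frame: state, tp, fn, fp, tn, sensitivity, specificity.
#' @export
recovery_metrics <- function(calls_by_group, truth_state) {
  groups <- intersect(colnames(truth_state), names(calls_by_group))
  if (!length(groups)) stop2("no overlapping groups between calls and truth")
  rows <- lapply(STATES, function(st) {
    tp <- fn <- fp <- tn <- 0L
    for (g in groups) {
      calls <- calls_by_group[[g]]
      tr <- truth_state[match(calls$probe_id, rownames(truth_state)), g]
      called <- calls$state == st
      is_true <- tr == st
      tp <- tp + sum(called & is_true); fn <- fn + sum(!called & is_true)
      fp <- fp + sum(called & !is_true); tn <- tn + sum(!called & !is_true)
    }
    data.frame(state = st, tp = tp, fn = fn, fp = fp, tn = tn,
               sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
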