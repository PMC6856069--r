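# Group mean methylation, hyper/hypo state calling at the +/-2 M-value
# cutoff, per-probe Welch differential methylation with BH FDR, top-K
# selection and hierarchical ordering for heatmaps.

#' Per-probe mean M-value within a sample group
#'
#' @param m numeric M-value matrix, probes x samples (sample ids as colnames).
#' @param sheet sample sheet data.frame (`sample_id`, `group`).
#' @param group group label to average over.
#' @return named numeric vector of per-probe means (missing values excluded
#'   per probe); attribute `n_used` carries the per-probe sample counts.
#' @export
group_mean_m <- function(m, sheet, group) {
  ids <- sheet$sample_id[sheet$group == group]
  ids <- intersect(colnames(m), ids)
  if (!length(ids)) stop2("no samples in group '", group, "'")
  sub <- m[, ids, drop = FALSE]
  out <- rowMeans(sub, na.rm = TRUE)
  attr(out, "n_used") <- rowSums(!is.na(sub))
  out
}

#' Call hyper/hypo/neither methylation states from mean M-values
#'
#' A probe is hypermethylated when mean M >= `hyper_min` (default +2,
#' beta 0.8), hypomethylated when mean M <= `hypo_max` (default -2,
#' beta 0.2), otherwise neither; boundary values are included.
#'
#' @param means named numeric vector of per-probe mean M-values.
#' @param hyper_min,hypo_max state-calling cutoffs on the M scale.
#' @return data.frame: `probe_id`, `mean_m`, `state` in
#'   `{"hyper","hypo","neither"}`.
#' @export
call_states <- function(means, hyper_min = 2, hypo_max = -2) {
  if (hyper_min <= hypo_max) stop2("hyper_min must exceed hypo_max")
  if (any(!is.finite(means))) stop2("non-finite mean M-values")
  state <- ifelse(means >= hyper_min, "hyper",
                  ifelse(means <= hypo_max, "hypo", "neither"))
  data.frame(probe_id = names(means) %||% as.character(seq_along(means)),
             mean_m = unname(means), state = unname(state),
             stringsAsFactors = FALSE)
}

# Vectorized Welch statistics for all rows at once; the workhorse behind
# welch_t_per_probe and row-wise use elsewhere. Degenerate rows (zero
# variance on both sides) get t = 0, p = 1 when means are equal, else
# p = 0, and are flagged.
row_welch <- function(a, b) {
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- apply(a, 1, stats::var, na.rm = TRUE)
  vb <- apply(b, 1, stats::var, na.rm = TRUE)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  degenerate <- se2 == 0
  p <- 2 * stats::pt(-abs(t), df)
  t[degenerate & ma == mb] <- 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  df[degenerate] <- NA_real_
  list(mean_a = ma, mean_b = mb, delta_m = ma - mb, t = t, df = df, p = p,
       degenerate = degenerate)
}

#' Per-probe Welch t-tests between two sample groups
#'
#' Two-sided unequal-variance t-test on M-values with Welch-Satterthwaite
#' degrees of freedom, computed row-wise. Probes with zero variance in both
#' groups and equal means get p = 1 by convention and are flagged.
#'
#' @inheritParams group_mean_m
#' @param group_a,group_b the two group labels (delta is A - B).
#' @return data.frame: probe_id, mean_a, mean_b, delta_m, t, df, p,
#'   degenerate.
#' @export
welch_t_per_probe <- function(m, sheet, group_a, group_b) {
  ia <- intersect(colnames(m), sheet$sample_id[sheet$group == group_a])
  ib <- intersect(colnames(m), sheet$sample_id[sheet$group == group_b])
  if (length(ia) < 2 || length(ib) < 2)
    stop2("need >= 2 samples per group for Welch tests")
  w <- row_welch(m[, ia, drop = FALSE], m[, ib, drop = FALSE])
  data.frame(probe_id = rownames(m) %||% as.character(seq_len(nrow(m))),
             mean_a = unname(w$mean_a), mean_b = unname(w$mean_b),
             delta_m = unname(w$delta_m), t = unname(w$t), df = unname(w$df),
             p = unname(w$p), degenerate = unname(w$degenerate),
             stringsAsFactors = FALSE)
}

#' False-discovery-rate adjustment
#'
#' Step-up Benjamini-Hochberg q-values (or Benjamini-Yekutieli when
#' requested): q_(i) = min over j >= i of min(1, m p_(j) / j).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop2("p-values outside [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Two-group differential methylation
#'
#' [welch_t_per_probe()] followed by [bh_fdr()]; significance at q below the
#' FDR threshold, with the direction of the mean difference recorded as
#' hyper- or hypomethylated in group A.
#'
#' @inheritParams welch_t_per_probe
#' @param fdr significance threshold on the BH q-value (default 0.05).
#' @param method FDR method, see [bh_fdr()].
#' @return data.frame extending the Welch table with `q`, `significant` and
#'   `direction` (`"hyper_in_a"` / `"hypo_in_a"`).
#' @export
diff_methylation <- function(m, sheet, group_a, group_b, fdr = 0.05,
                             method = "BH") {
  res <- welch_t_per_probe(m, sheet, group_a, group_b)
  res$q <- bh_fdr(res$p, method)
  res$significant <- res$q < fdr
  res$direction <- ifelse(res$delta_m >= 0, "hyper_in_a", "hypo_in_a")
  res
}

#' Select the top-K most differential probes
#'
#' Orders by ascending q, breaking ties by larger |delta M| and then
#' lexicographic probe id so the selection is deterministic.
#'
#' @param result a [diff_methylation()] table (needs `q`, `delta_m`,
#'   `probe_id`).
#' @param k number of probes to return (default 10000).
#' @return character vector of probe ids, best first.
#' @export
top_k_probes <- function(result, k = 10000) {
  if (!is_count(k) || k <= 0) stop2("k must be a positive integer")
  if (k > nrow(result)) stop2("k exceeds the number of probes")
  o <- order(result$q, -abs(result$delta_m), result$probe_id)
  result$probe_id[o][seq_len(k)]
}

#' Deterministic hierarchical leaf orders for a heatmap
#'
#' Agglomerative clustering (Euclidean distance, complete linkage by
#' default) of samples (columns) and probes (rows).
#'
#' @param mat numeric matrix, probes x samples (>= 2 samples).
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `sample_order` and `probe_order` (leaf index vectors)
#'   and the two dendrograms (`sample_hclust`, `probe_hclust`).
#' @export
hierarchical_order <- function(mat, linkage = "complete") {
  if (ncol(mat) < 2) stop2("need >= 2 samples to cluster")
  if (all(mat == mat[1])) warning("constant matrix: leaf order is arbitrary (but deterministic)")
  hs <- stats::hclust(stats::dist(t(mat)), method = linkage)
  hp <- if (nrow(mat) >= 2) stats::hclust(stats::dist(mat), method = linkage) else NULL
  list(sample_order = hs$order,
       probe_order = if (is.null(hp)) seq_len(nrow(mat)) else hp$order,
       sample_hclust = hs, probe_hclust = hp)
}

#' Hyper/hypo counts per functional region among significant probes
#'
#' Counts significant differential probes by direction within each
#' functional region; a probe annotated to several regions is counted in
#' each (multi-membership duplication).
#'
#' @param result a [diff_methylation()] table.
#' @param manifest manifest data.frame covering the probes.
#' @return data.frame: region, hyper (count, hyper in group A), hypo.
#' @export
region_direction_counts <- function(result, manifest) {
  sig <- result[result$significant, , drop = FALSE]
  out <- data.frame(region = REGIONS, hyper = 0L, hypo = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(sig)) {
    idx <- match(sig$probe_id, manifest$probe_id)
    for (i in seq_along(REGIONS)) {
      inreg <- manifest[[REGIONS[i]]][idx]
      inreg[is.na(inreg)] <- FALSE
      out$hyper[i] <- sum(inreg & sig$direction == "hyper_in_a")
      out$hypo[i] <- sum(inreg & sig$direction == "hypo_in_a")
    }
  }
  out
}
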