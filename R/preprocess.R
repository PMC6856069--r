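# Sample QC, probe filtering, platform harmonization, normalization and
# beta <-> M conversion.

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)) after clamping beta into
#' `[epsilon, 1 - epsilon]` to avoid infinities at fully (un)methylated
#' probes. Beta 0.8 maps to M = +2 and beta 0.2 to M = -2, the
#' correspondence behind the state-calling cutoffs.
#'
#' @param beta numeric vector or matrix in `[0, 1]`.
#' @param epsilon clamp half-width (small positive).
#' @param tol tolerance for out-of-range input before erroring.
#' @return M-values, same shape as `beta`.
#' @seealso [m_to_beta()]
#' @export
beta_to_m <- function(beta, epsilon = 1e-6, tol = 1e-8) {
  if (any(beta < -tol | beta > 1 + tol, na.rm = TRUE))
    stop2("beta values outside [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M-values to beta values
#'
#' Inverse logit2: beta = 2^M / (1 + 2^M). Exact inverse of [beta_to_m()]
#' away from the clamp boundary.
#'
#' @param m numeric vector or matrix of finite M-values.
#' @return beta values in (0, 1), same shape as `m`.
#' @export
m_to_beta <- function(m) {
  # 1 / (1 + 2^-M) is stable for large |M|
  1 / (1 + 2^(-m))
}

#' Sample quality control on detection p-values
#'
#' A sample is kept iff its mean detection p-value is strictly below the
#' threshold (default 0.01).
#'
#' @param detection_p numeric matrix of detection p-values, probes x samples,
#'   with sample ids as column names.
#' @param threshold QC cutoff on the per-sample mean.
#' @return list with `report` (data.frame: sample_id, mean_detection_p, kept,
#'   threshold) and `kept` (character vector of retained sample ids).
#' @export
qc_filter_samples <- function(detection_p, threshold = 0.01) {
  if (is.null(dim(detection_p)) || any(dim(detection_p) == 0))
    stop2("detection p-value matrix is empty")
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
    stop2("detection p-values outside [0, 1]")
  mp <- colMeans(detection_p, na.rm = TRUE)
  report <- data.frame(sample_id = colnames(detection_p) %||% as.character(seq_along(mp)),
                       mean_detection_p = unname(mp),
                       kept = unname(mp < threshold),
                       threshold = threshold,
                       stringsAsFactors = FALSE)
  list(report = report, kept = report$sample_id[report$kept])
}

#' Harmonize array platforms to their shared probe universe
#'
#' Intersects the probe sets of two or more platform manifests; the result is
#' the analysis universe every downstream stage works on. Probe order is
#' stable by genomic position (chromosome order of the first manifest, then
#' position).
#'
#' @param ... two or more manifest data.frames (or a single list of them).
#' @return character vector of shared probe ids, position-ordered.
#' @export
harmonize_platforms <- function(...) {
  mans <- list(...)
  if (length(mans) == 1 && is.list(mans[[1]]) && !is.data.frame(mans[[1]]))
    mans <- mans[[1]]
  if (length(mans) < 2) stop2("need at least two platform manifests")
  ids <- Reduce(intersect, lapply(mans, `[[`, "probe_id"))
  if (!length(ids)) stop2("platforms share no probes")
  ref <- mans[[1]]
  ref <- ref[ref$probe_id %in% ids, , drop = FALSE]
  ref$probe_id[order(match(ref$chromosome, unique(ref$chromosome)), ref$position)]
}

#' Split a combined manifest into per-platform manifests
#'
#' Convenience for manifests carrying `platform_450k` / `platform_epic`
#' flags (as the synthetic generator emits).
#'
#' @param manifest combined manifest data.frame.
#' @return named list of manifests, one per platform with any probes.
#' @export
split_platforms <- function(manifest) {
  out <- list(A450K = manifest[manifest$platform_450k, , drop = FALSE],
              EPIC = manifest[manifest$platform_epic, , drop = FALSE])
  out[vapply(out, nrow, integer(1)) > 0]
}

#' Quantile normalize a methylation matrix
#'
#' Forces every column onto the mean quantile vector (ties share the mean of
#' their quantile slots), preserving within-column rank order; computation is
#' delegated to `limma::normalizeQuantiles`. An optional stratification
#' vector (e.g. Infinium probe design type) normalizes within strata
#' separately.
#'
#' @param mat numeric matrix, probes x samples.
#' @param stratify optional vector (length = rows) of stratum labels.
#' @return normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(mat, stratify = NULL) {
  if (is.null(dim(mat))) stop2("expected a matrix")
  if (ncol(mat) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(mat)
  }
  if (is.null(stratify)) return(limma::normalizeQuantiles(mat, ties = TRUE))
  stopifnot(length(stratify) == nrow(mat))
  out <- mat
  for (s in unique(stratify)) {
    sel <- stratify == s
    out[sel, ] <- if (sum(sel) == 1) mat[sel, , drop = FALSE] else
      limma::normalizeQuantiles(mat[sel, , drop = FALSE], ties = TRUE)
  }
  out
}

#' Read a probes-x-samples matrix from tab-separated text
#'
#' First column must be the probe id; remaining columns are samples.
#'
#' @param path file path.
#' @return numeric matrix with probe ids as rownames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a probes-x-samples matrix to tab-separated text
#'
#' @param mat numeric matrix with probe-id rownames.
#' @param path output path.
#' @param id_col name for the probe id column.
#' @export
write_matrix <- function(mat, path, id_col = "probe_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a sample sheet
#'
#' Tab-separated with columns `sample_id`, `group`, `platform`.
#'
#' @param path file path.
#' @return data.frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "group", "platform"), names(df))
  if (length(need)) stop2("sample sheet missing column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop2("duplicated sample_id in sheet")
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
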