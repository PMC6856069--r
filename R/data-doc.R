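#' Reported probe counts for six IDH1/2-mutant tumor cohorts
#'
#' Published per-tumor-type totals of hyper- and hypomethylated probes
#' (mean M-value beyond +/-2 over the cross-platform probe universe) and
#' the tumor-type-specific (unique) subsets, for IDH1/2-mutant acute
#' myeloid leukemia, astrocytoma, oligodendroglioma, solid papillary breast
#' carcinoma with reverse polarity, cholangiocarcinoma and sinonasal
#' undifferentiated carcinoma. Used as the input to
#' [specificity_from_counts()] when reproducing the printed specificity
#' percentages.
#'
#' @return data.frame with columns `group`, `state`, `total`, `unique`.
#' @examples
#' specificity_from_counts(idh_tumor_probe_counts())
#' @export
idh_tumor_probe_counts <- function() {
  utils::read.table(
    system.file("extdata", "idh_tumor_probe_counts.tsv", package = "methtopo"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
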