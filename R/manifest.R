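# Probe manifest: per-probe location, functional-region membership, gene
# symbols and platform flags. Internal representation is a plain data.frame:
#   probe_id, chromosome, position (1-based), strand, promoter, gene_body,
#   enhancer (logical), genes (";"-separated), platform_450k, platform_epic.

REGIONS <- c("promoter", "gene_body", "enhancer")

#' Validate a probe manifest
#'
#' @param manifest data.frame with columns `probe_id`, `chromosome`,
#'   `position`, `strand`, `promoter`, `gene_body`, `enhancer`, `genes`,
#'   `platform_450k`, `platform_epic`.
#' @param genome optional [genome_table()]; when given, chromosomes are
#'   checked against it.
#' @return the manifest, invisibly, after validation.
#' @export
validate_manifest <- function(manifest, genome = NULL) {
  need <- setdiff(c("probe_id", "chromosome", "position", "strand",
                    REGIONS, "genes", "platform_450k", "platform_epic"),
                  names(manifest))
  if (length(need)) stop2("manifest is missing column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$probe_id)) stop2("duplicated probe_id in manifest")
  if (any(manifest$position < 1)) stop2("probe positions must be >= 1")
  if (!is.null(genome)) {
    bad <- setdiff(unique(manifest$chromosome), genome$chromosomes$chrom)
    if (length(bad)) stop2("manifest chromosome(s) not in genome: ", paste(bad, collapse = ", "))
  }
  invisible(manifest)
}

#' Read a probe manifest from delimited text
#'
#' Adapts Illumina-style annotation headers through a column-mapping config.
#' The promoter flag is derived from the UCSC RefGene group string (any entry
#' in `promoter_groups`, default `TSS200`: within 200 bp of a transcription
#' start site), gene body from `body_groups` (default `Body`), enhancer from
#' a truthy enhancer column.
#'
#' @param path file path (tab-separated by default).
#' @param column_map named list mapping internal names to file column names;
#'   recognised keys: `probe_id`, `chr`, `pos`, `strand`, `refgene_group`,
#'   `enhancer`, `genes`, `platform` (or the pair `platform_450k` /
#'   `platform_epic`).
#' @param promoter_groups,body_groups RefGene group labels mapped to the
#'   promoter / gene-body flags.
#' @param sep field separator.
#' @return a validated manifest data.frame.
#' @export
read_manifest <- function(path,
                          column_map = list(
                            probe_id = "probe_id", chr = "chr", pos = "pos",
                            strand = "strand", refgene_group = "UCSC_RefGene_Group",
                            enhancer = "Enhancer", genes = "UCSC_RefGene_Name",
                            platform = "platform"),
                          promoter_groups = "TSS200",
                          body_groups = "Body",
                          sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE, quote = "")
  internal <- c("probe_id", "chromosome", "position", "strand", REGIONS,
                "genes", "platform_450k", "platform_epic")
  if (all(internal %in% names(df))) {
    # native schema (as written by write_manifest): take columns as-is
    out <- df[internal]
    out$position <- as.integer(out$position)
    for (cc in c(REGIONS, "platform_450k", "platform_epic"))
      out[[cc]] <- as.logical(out[[cc]])
    out$genes[is.na(out$genes)] <- ""
    validate_manifest(out)
    return(out)
  }
  col <- function(key) {
    nm <- column_map[[key]]
    if (is.null(nm) || !nm %in% names(df)) return(NULL)
    df[[nm]]
  }
  grp <- col("refgene_group") %||% ""
  has_group <- function(x, groups)
    vapply(strsplit(as.character(x), ";", fixed = TRUE),
           function(g) any(g %in% groups), logical(1))
  enh <- col("enhancer")
  enh <- if (is.null(enh)) rep(FALSE, nrow(df)) else {
    if (is.logical(enh)) enh else toupper(as.character(enh)) %in% c("TRUE", "1", "YES")
  }
  plat <- col("platform")
  if (!is.null(plat)) {
    plat <- strsplit(as.character(plat), ";", fixed = TRUE)
    p450 <- vapply(plat, function(p) "A450K" %in% p, logical(1))
    pepic <- vapply(plat, function(p) "EPIC" %in% p, logical(1))
  } else {
    p450 <- as.logical(col("platform_450k") %||% rep(TRUE, nrow(df)))
    pepic <- as.logical(col("platform_epic") %||% rep(TRUE, nrow(df)))
  }
  out <- data.frame(
    probe_id = as.character(col("probe_id")),
    chromosome = as.character(col("chr")),
    position = as.integer(col("pos")),
    strand = as.character(col("strand") %||% rep("*", nrow(df))),
    promoter = has_group(grp, promoter_groups),
    gene_body = has_group(grp, body_groups),
    enhancer = enh,
    genes = as.character(col("genes") %||% rep("", nrow(df))),
    platform_450k = p450,
    platform_epic = pepic,
    stringsAsFactors = FALSE)
  validate_manifest(out)
  out
}

#' Write a manifest to tab-separated text
#'
#' @param manifest manifest data.frame.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Remove sex-chromosome probes
#'
#' Drops every probe on chrX or chrY; autosomal probes are untouched.
#'
#' @param manifest manifest data.frame.
#' @param sex_chromosomes labels treated as sex chromosomes.
#' @return the filtered manifest.
#' @export
drop_sex_probes <- function(manifest, sex_chromosomes = c("chrX", "chrY")) {
  manifest[!manifest$chromosome %in% sex_chromosomes, , drop = FALSE]
}

#' Probe ids belonging to a functional region
#'
#' A probe annotated to several regions appears in the list of each region;
#' probes with no region annotation appear in none.
#'
#' @param manifest manifest data.frame.
#' @param region one of `"promoter"`, `"gene_body"`, `"enhancer"`.
#' @return character vector of probe ids.
#' @export
region_probes <- function(manifest, region) {
  region <- match.arg(region, REGIONS)
  manifest$probe_id[manifest[[region]]]
}
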