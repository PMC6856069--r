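# Genome bookkeeping: chromosomes, centromeres, cytobands, arm/band lookup.
#
# Coordinate conventions: UCSC-text tables (gap, cytoBand) are 0-based
# half-open and are kept that way internally; probe positions are 1-based
# (Illumina manifest convention) and converted once (pos - 1) at lookup /
# export time. BED/bedGraph output is therefore bit-exact 0-based half-open.

#' Construct and validate a genome table
#'
#' Bundles chromosome lengths, centromere intervals (UCSC gap-table style)
#' and a cytoband tiling into the single object all topographic operations
#' consume.
#'
#' @param chromosomes data.frame with columns `chrom`, `length` (bp). Row
#'   order defines the genome ordering used for sorting output.
#' @param centromeres data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per chromosome.
#' @param cytobands data.frame with columns `chrom`, `start`, `end`, `band`,
#'   `stain`; bands must tile each chromosome without gaps or overlap.
#' @return object of class `genome_table`.
#' @export
genome_table <- function(chromosomes, centromeres, cytobands) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop2(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  need(chromosomes, c("chrom", "length"), "chromosomes")
  need(centromeres, c("chrom", "start", "end"), "centromeres")
  need(cytobands, c("chrom", "start", "end", "band", "stain"), "cytobands")

  chromosomes$chrom <- as.character(chromosomes$chrom)
  centromeres$chrom <- as.character(centromeres$chrom)
  cytobands$chrom <- as.character(cytobands$chrom)

  if (anyDuplicated(chromosomes$chrom)) stop2("duplicated chromosome labels")
  lens <- stats::setNames(chromosomes$length, chromosomes$chrom)

  bad <- setdiff(centromeres$chrom, chromosomes$chrom)
  if (length(bad)) stop2("centromere rows for unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(centromeres$chrom)) stop2("more than one centromere interval per chromosome")
  with(centromeres, {
    if (any(start < 0 | end > lens[chrom] | start > end))
      stop2("centromere interval not contained in its chromosome")
  })

  # cytobands must tile [0, length) per chromosome
  for (ch in chromosomes$chrom) {
    b <- cytobands[cytobands$chrom == ch, , drop = FALSE]
    if (!nrow(b)) stop2("no cytobands for chromosome ", ch)
    b <- b[order(b$start), , drop = FALSE]
    if (b$start[1] != 0 || b$end[nrow(b)] != lens[[ch]] ||
        (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)])))
      stop2("cytobands do not tile chromosome ", ch)
  }

  structure(
    list(chromosomes = chromosomes,
         centromeres = centromeres[match(chromosomes$chrom, centromeres$chrom), , drop = FALSE],
         cytobands = cytobands[order(match(cytobands$chrom, chromosomes$chrom), cytobands$start), ,
                               drop = FALSE]),
    class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat("genome_table:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$cytobands), "cytobands\n")
  invisible(x)
}

#' Read a UCSC gap table and extract centromeres
#'
#' Accepts the full 9-column `gap` dialect (bin, chrom, chromStart, chromEnd,
#' ix, n, size, type, bridge) or a minimal 4-column (chrom, start, end, type)
#' file, headered or not; keeps `type == "centromere"` rows only.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
read_gap_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) >= 9) {
    out <- data.frame(chrom = as.character(df[[2]]), start = df[[3]], end = df[[4]],
                      type = as.character(df[[8]]), stringsAsFactors = FALSE)
  } else if (ncol(df) == 4) {
    out <- stats::setNames(df, c("chrom", "start", "end", "type"))
    out$chrom <- as.character(out$chrom)
  } else {
    stop2("unrecognized gap-table layout (", ncol(df), " columns)")
  }
  out <- out[out$type == "centromere", c("chrom", "start", "end")]
  rownames(out) <- NULL
  out
}

#' Read a UCSC cytoBand table
#'
#' Five tab-separated columns: chrom, chromStart, chromEnd, name, gieStain
#' (0-based half-open), with or without a `#`-prefixed header.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `band`, `stain`.
#' @export
read_cytoband_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 5) stop2("cytoBand table must have 5 columns, found ", ncol(df))
  stats::setNames(df, c("chrom", "start", "end", "band", "stain"))
}

#' Assign probes to chromosome arms
#'
#' A position is on the p arm if it lies strictly before the centromere gap,
#' on the q arm if at or beyond its end, and on no arm (`NA`) inside the gap.
#' Arm labels concatenate chromosome and arm, e.g. `"chr1p"`.
#'
#' @param chrom character vector of chromosome labels.
#' @param position 1-based positions, same length as `chrom`.
#' @param genome a [genome_table()].
#' @return character vector of arm labels (`NA` for centromeric positions).
#' @export
arm_of <- function(chrom, position, genome) {
  chrom <- as.character(chrom)
  bad <- setdiff(unique(chrom), genome$chromosomes$chrom)
  if (length(bad)) stop2("unknown chromosome(s): ", paste(bad, collapse = ", "))
  idx <- match(chrom, genome$centromeres$chrom)
  cs <- genome$centromeres$start[idx]
  ce <- genome$centromeres$end[idx]
  pos0 <- position - 1L
  ifelse(pos0 < cs, paste0(chrom, "p"),
         ifelse(pos0 >= ce, paste0(chrom, "q"), NA_character_))
}

#' Assign probes to cytobands
#'
#' Bands are half-open `[start, end)` intervals: a position equal to a band
#' boundary belongs to the following band.
#'
#' @inheritParams arm_of
#' @return character vector of band names.
#' @export
band_of <- function(chrom, position, genome) {
  chrom <- as.character(chrom)
  bad <- setdiff(unique(chrom), genome$chromosomes$chrom)
  if (length(bad)) stop2("unknown chromosome(s): ", paste(bad, collapse = ", "))
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  pos0 <- position - 1L
  if (any(pos0 < 0 | pos0 >= lens[chrom]))
    stop2("position beyond chromosome length")
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    b <- genome$cytobands[genome$cytobands$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    out[sel] <- b$band[findInterval(pos0[sel], b$start)]
  }
  out
}

#' Annotate a manifest with arm and band assignments
#'
#' Adds `arm` and `band` columns (see [arm_of()], [band_of()]); centromeric
#' probes get `NA` arm and their (acen) band.
#'
#' @param manifest a probe manifest data.frame with `chromosome`, `position`.
#' @param genome a [genome_table()].
#' @return the manifest with `arm` and `band` columns appended.
#' @export
assign_arms <- function(manifest, genome) {
  manifest$arm <- arm_of(manifest$chromosome, manifest$position, genome)
  manifest$band <- band_of(manifest$chromosome, manifest$position, genome)
  manifest
}
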