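# Topography: per-arm region ratios, genome-wide region ratios with paired
# tests, bootstrap arm-vs-genome tests, desert-band detection and track
# export.

#' Default acrocentric p-arm exclusion list
#'
#' The short arms of the human acrocentric chromosomes carry essentially no
#' array probes and are excluded from arm-ratio analyses.
#' @export
ACROCENTRIC_P_ARMS <- c("chr13p", "chr14p", "chr15p", "chr21p", "chr22p")

# arms present in a genome, in genome order (p then q per chromosome)
genome_arms <- function(genome) {
  as.vector(t(outer(genome$chromosomes$chrom, c("p", "q"), paste0)))
}

#' Per-arm functional-region methylation ratios
#'
#' For every (chromosome arm x functional region x state): the number of
#' common state probes annotated to the region on that arm, over all region
#' probes on the arm. Multi-region probes contribute to each of their
#' regions; acrocentric p-arms are excluded.
#'
#' @param common_sets named list with `hyper` and `hypo` probe-id vectors
#'   (e.g. from [common_probes()]).
#' @param manifest arm-assigned manifest (see [assign_arms()]).
#' @param genome a [genome_table()].
#' @param exclude_arms arm labels to exclude (default the acrocentric
#'   p-arms; arms absent from the genome are ignored).
#' @return data.frame: arm, region, state, numerator, denominator, ratio
#'   (NA when the denominator is 0, with a warning on non-excluded arms),
#'   excluded.
#' @export
arm_ratios <- function(common_sets, manifest, genome,
                       exclude_arms = ACROCENTRIC_P_ARMS) {
  if (is.null(manifest$arm)) stop2("manifest has no arm assignment; run assign_arms()")
  arms <- genome_arms(genome)
  grid <- expand.grid(arm = arms, region = REGIONS, state = STATES,
                      stringsAsFactors = FALSE)
  grid$excluded <- grid$arm %in% exclude_arms
  num <- den <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    on_arm <- !is.na(manifest$arm) & manifest$arm == grid$arm[i] &
      manifest[[grid$region[i]]]
    den[i] <- sum(on_arm)
    num[i] <- sum(manifest$probe_id[on_arm] %in% common_sets[[grid$state[i]]])
  }
  grid$numerator <- num
  grid$denominator <- den
  grid$ratio <- ifelse(grid$excluded | den == 0, NA_real_, num / den)
  zero <- !grid$excluded & den == 0
  if (any(zero))
    warning("zero region-probe coverage on non-excluded arm(s): ",
            paste(unique(grid$arm[zero]), collapse = ", "))
  grid[c("arm", "region", "state", "numerator", "denominator", "ratio", "excluded")]
}

#' Genome-wide region ratios and pairwise paired tests across arms
#'
#' Per (region x state), the genome-wide ratio (summing numerators and
#' denominators over non-excluded arms) plus two-sided paired t-tests
#' between regions, pairing on chromosome arm.
#'
#' @param arm_table an [arm_ratios()] table.
#' @return list: `ratios` (region, state, numerator, denominator, ratio) and
#'   `tests` (state, region_a, region_b, mean_diff, t, p, degenerate) where
#'   a constant per-arm difference yields a degenerate flagged record.
#' @export
genomewide_region_ratios <- function(arm_table) {
  keep <- !arm_table$excluded
  tab <- arm_table[keep, , drop = FALSE]
  ratios <- do.call(rbind, lapply(split(tab, tab[c("region", "state")]), function(d)
    data.frame(region = d$region[1], state = d$state[1],
               numerator = sum(d$numerator), denominator = sum(d$denominator),
               ratio = sum(d$numerator) / sum(d$denominator),
               stringsAsFactors = FALSE)))
  rownames(ratios) <- NULL

  pairs <- utils::combn(REGIONS, 2)
  tests <- do.call(rbind, lapply(STATES, function(st) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- tab[tab$state == st & tab$region == pairs[1, j], ]
      b <- tab[tab$state == st & tab$region == pairs[2, j], ]
      b <- b[match(a$arm, b$arm), ]
      ok <- !is.na(a$ratio) & !is.na(b$ratio)
      d <- a$ratio[ok] - b$ratio[ok]
      if (length(d) < 2) stop2("need >= 2 paired arms")
      # matches t.test's own "essentially constant" guard
      degen <- stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.xmin)
      if (degen) {
        tt <- list(statistic = NA_real_, p.value = NA_real_)
      } else {
        tt <- stats::t.test(a$ratio[ok], b$ratio[ok], paired = TRUE)
      }
      data.frame(state = st, region_a = pairs[1, j], region_b = pairs[2, j],
                 mean_diff = mean(d), t = unname(tt$statistic), p = tt$p.value,
                 n_arms = length(d), degenerate = degen, stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL
  list(ratios = ratios, tests = tests)
}

#' Arm-versus-genome ratio tests with bootstrap replicates
#'
#' The per-arm ratio is a single number, so replicates are generated by
#' bootstrap resampling probes: for each (arm x region x state), B resamples
#' of the arm's region probes give arm replicates, B resamples of all
#' (non-excluded) region probes give genome replicates, and a two-sided
#' Welch t-test compares the two. BH adjustment is applied across arms
#' within each (region x state).
#'
#' @inheritParams arm_ratios
#' @param b number of bootstrap replicates (default 200).
#' @param seed integer seed; the resampling is fully reproducible.
#' @return data.frame: arm, region, state, arm_ratio, genome_ratio, t, p, q,
#'   degenerate.
#' @export
arm_vs_genome_test <- function(common_sets, manifest, genome, b = 200,
                               seed = 1, exclude_arms = ACROCENTRIC_P_ARMS) {
  if (is.null(manifest$arm)) stop2("manifest has no arm assignment; run assign_arms()")
  set.seed(seed)
  arms <- setdiff(genome_arms(genome), exclude_arms)
  out <- list()
  for (st in STATES) {
    common <- common_sets[[st]]
    for (rg in REGIONS) {
      inreg <- !is.na(manifest$arm) & manifest[[rg]] & !manifest$arm %in% exclude_arms
      hit <- manifest$probe_id %in% common & inreg
      hit_all <- hit[inreg]
      arm_all <- manifest$arm[inreg]
      boot_ratio <- function(x, b) {
        n <- length(x)
        vapply(seq_len(b), function(i) mean(x[sample.int(n, n, replace = TRUE)]),
               numeric(1))
      }
      gen_rep <- boot_ratio(hit_all, b)
      for (a in intersect(arms, unique(arm_all))) {
        x <- hit_all[arm_all == a]
        if (length(x) < 2) next
        arm_rep <- boot_ratio(x, b)
        degen <- stats::var(arm_rep) == 0 && stats::var(gen_rep) == 0
        if (degen) {
          t <- if (mean(arm_rep) == mean(gen_rep)) 0 else NA_real_
          p <- if (mean(arm_rep) == mean(gen_rep)) 1 else 0
        } else {
          tt <- stats::t.test(arm_rep, gen_rep, var.equal = FALSE)
          t <- unname(tt$statistic); p <- tt$p.value
        }
        out[[length(out) + 1]] <- data.frame(
          arm = a, region = rg, state = st,
          arm_ratio = mean(x), genome_ratio = mean(hit_all),
          t = t, p = p, degenerate = degen, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res$q <- NA_real_
  for (st in STATES) for (rg in REGIONS) {
    sel <- res$state == st & res$region == rg
    res$q[sel] <- bh_fdr(res$p[sel])
  }
  res
}

#' Detect methylation-desert cytobands
#'
#' A band is a desert when it carries adequate probe coverage (>= `min_probes`
#' probes with at least one functional-region annotation) yet contains zero
#' commonly hyper- or hypomethylated probes in any of the three regions. The
#' coverage guard prevents flagging bands that simply lack probes.
#'
#' @inheritParams arm_ratios
#' @param min_probes minimum annotated-probe coverage for desert eligibility
#'   (default 50).
#' @return data.frame: chrom, band, coverage (annotated probes), common_hyper,
#'   common_hypo (counts over the three regions), desert flag.
#' @export
desert_bands <- function(common_sets, manifest, genome, min_probes = 50) {
  if (is.null(manifest$band)) stop2("manifest has no band assignment; run assign_arms()")
  annotated <- manifest$promoter | manifest$gene_body | manifest$enhancer
  key <- paste(manifest$chromosome, manifest$band, sep = ":")
  bands <- genome$cytobands
  bkey <- paste(bands$chrom, bands$band, sep = ":")
  cov <- tapply(annotated, key, sum)
  n_state <- function(st) {
    hit <- annotated & manifest$probe_id %in% common_sets[[st]]
    tapply(hit, key, sum)
  }
  nh <- n_state("hyper"); nl <- n_state("hypo")
  out <- data.frame(chrom = bands$chrom, band = bands$band,
                    coverage = as.integer(ifelse(is.na(cov[bkey]), 0, cov[bkey])),
                    common_hyper = as.integer(ifelse(is.na(nh[bkey]), 0, nh[bkey])),
                    common_hypo = as.integer(ifelse(is.na(nl[bkey]), 0, nl[bkey])),
                    stringsAsFactors = FALSE)
  out$desert <- out$coverage >= min_probes & out$common_hyper == 0 & out$common_hypo == 0
  out
}

#' Export common-probe methylation tracks
#'
#' One bedGraph per (region x state) carrying mean M-values clipped,
#' sign-preserving, into the display range (default |M| in [1.9, 7]), plus a
#' BED of desert bands. Records are 0-based half-open, 1 bp per probe,
#' position-sorted.
#'
#' @param common_sets named list with `hyper` / `hypo` probe ids.
#' @param mean_m named numeric vector of per-probe mean M-values (across the
#'   groups), covering the common probes.
#' @param manifest arm-assigned manifest.
#' @param genome a [genome_table()].
#' @param dir output directory (created if missing).
#' @param clip two positive numbers, the |M| display range.
#' @param deserts optional [desert_bands()] table; flagged bands are written
#'   to `desert_bands.bed`.
#' @return invisibly, the vector of files written.
#' @export
export_tracks <- function(common_sets, mean_m, manifest, genome, dir,
                          clip = c(1.9, 7), deserts = NULL) {
  bad <- setdiff(unique(manifest$chromosome), genome$chromosomes$chrom)
  if (length(bad)) stop2("unknown chromosome(s) in manifest: ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (st in STATES) for (rg in REGIONS) {
    ids <- intersect(common_sets[[st]], region_probes(manifest, rg))
    m <- manifest[match(ids, manifest$probe_id), , drop = FALSE]
    val <- unname(mean_m[ids])
    val <- sign(val) * pmin(pmax(abs(val), clip[1]), clip[2])
    df <- data.frame(chrom = m$chromosome, start = m$position - 1L,
                     end = m$position, value = val, stringsAsFactors = FALSE)
    df <- df[order(match(df$chrom, genome$chromosomes$chrom), df$start), , drop = FALSE]
    f <- file.path(dir, sprintf("common_%s_%s.bedGraph", st, rg))
    write_bedgraph(df, f)
    files <- c(files, f)
  }
  if (!is.null(deserts)) {
    d <- deserts[deserts$desert, , drop = FALSE]
    b <- genome$cytobands[match(paste(d$chrom, d$band),
                                paste(genome$cytobands$chrom, genome$cytobands$band)), ]
    f <- file.path(dir, "desert_bands.bed")
    write_bed(data.frame(chrom = b$chrom, start = b$start, end = b$end,
                         name = paste0(b$chrom, b$band), stringsAsFactors = FALSE), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write / read bedGraph and BED files
#'
#' Plain tab-separated, no header (an optional `track` line for bedGraph),
#' 0-based half-open coordinates; [read_bedgraph()] inverts [write_bedgraph()]
#' exactly.
#'
#' @param df data.frame with columns chrom, start, end, value (bedGraph) or
#'   chrom, start, end, name (BED).
#' @param path output path.
#' @param track_line optional character track definition line.
#' @export
write_bedgraph <- function(df, path, track_line = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  utils::write.table(df[c("chrom", "start", "end", "value")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track")]
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df, c("chrom", "start", "end", "value"))
}

#' @rdname write_bedgraph
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
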