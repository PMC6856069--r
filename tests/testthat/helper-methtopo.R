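# Shared fixtures, all built in code.

# two-chromosome toy genome: chrA 1000 bp (centromere 400-600),
# chrB 600 bp acrocentric-style (centromere 0-100)
tiny_genome <- function() {
  genome_table(
    chromosomes = data.frame(chrom = c("chrA", "chrB"), length = c(1000, 600)),
    centromeres = data.frame(chrom = c("chrA", "chrB"),
                             start = c(400, 0), end = c(600, 100)),
    cytobands = rbind(
      data.frame(chrom = "chrA", start = c(0, 200, 400, 600, 800),
                 end = c(200, 400, 600, 800, 1000),
                 band = c("p2", "p1", "cen", "q1", "q2"),
                 stain = c("gneg", "gpos50", "acen", "gneg", "gpos50")),
      data.frame(chrom = "chrB", start = c(0, 100, 350),
                 end = c(100, 350, 600),
                 band = c("cen", "q1", "q2"),
                 stain = c("acen", "gneg", "gpos50"))))
}

tiny_manifest <- function(n = 20, chrom = "chrA", seed = 1) {
  set.seed(seed)
  data.frame(
    probe_id = sprintf("p%03d", seq_len(n)),
    chromosome = chrom,
    position = sort(sample(setdiff(1:1000, 401:600), n)),
    strand = "+",
    promoter = rep_len(c(TRUE, FALSE), n),
    gene_body = rep_len(c(FALSE, TRUE, TRUE, FALSE), n),
    enhancer = rep_len(c(FALSE, FALSE, TRUE), n),
    genes = sprintf("G%02d", rep_len(1:7, n)),
    platform_450k = TRUE, platform_epic = TRUE,
    stringsAsFactors = FALSE)
}

# default synthetic scenario + full pipeline run, computed once per session
default_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(synth_spec(), seed = 42)
      rep <- suppressWarnings(
        run_pipeline(ds$manifest, ds$beta, ds$detection_p, ds$sheet, ds$genome))
      cache <<- list(ds = ds, report = rep)
    }
    cache
  }
})

# independent step-up BH oracle (quadratic, by the definition)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) min(1, m * p[o[j]] / j))
    q_sorted[i] <- min(cand)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
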