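toy_arm_setup <- function() {
  g <- tiny_genome()
  man <- tiny_manifest(20)
  man <- assign_arms(man, g)
  list(genome = g, manifest = man)
}

test_that("arm ratios divide common region probes by region coverage per arm", {
  g <- tiny_genome()
  man <- tiny_manifest(20)
  man$promoter <- FALSE; man$gene_body <- FALSE
  man$enhancer <- c(rep(TRUE, 10), rep(FALSE, 10))
  man$position <- c(1:10 * 30, 601:610)  # 10 enhancer probes on chrAp
  man <- assign_arms(man, g)
  common <- list(hyper = man$probe_id[1:4], hypo = character(0))
  tab <- suppressWarnings(arm_ratios(common, man, g, exclude_arms = "chrBq"))
  row <- tab[tab$arm == "chrAp" & tab$region == "enhancer" & tab$state == "hyper", ]
  expect_equal(row$numerator, 4L)
  expect_equal(row$denominator, 10L)
  expect_equal(row$ratio, 0.4)
  # excluded arm carries no ratio
  excl <- tab[tab$arm == "chrBq", ]
  expect_true(all(excl$excluded) && all(is.na(excl$ratio)))
  expect_true(all(tab$numerator <= tab$denominator))
  expect_true(all(tab$ratio >= 0 & tab$ratio <= 1, na.rm = TRUE))
})

test_that("arm ratio conservation: arm numerators sum to the genome-wide count", {
  sc <- default_scenario()
  rep <- sc$report
  tab <- rep$arm_ratios
  for (st in c("hyper", "hypo")) for (rg in c("promoter", "gene_body", "enhancer")) {
    sel <- tab$state == st & tab$region == rg & !tab$excluded
    man <- rep$manifest
    genome_count <- sum(man$probe_id %in% rep$common[[st]] & man[[rg]] &
                          !is.na(man$arm) & !man$arm %in% rep$config$exclude_arms)
    expect_equal(sum(tab$numerator[sel]), genome_count)
  }
})

test_that("planted arm enrichment ranks the planted arm first", {
  rep <- default_scenario()$report
  tab <- rep$arm_ratios
  body_hyper <- tab[tab$state == "hyper" & tab$region == "gene_body" & !tab$excluded, ]
  expect_equal(body_hyper$arm[which.max(body_hyper$ratio)], "chr1q")
  at <- rep$arm_tests
  bh <- at[at$state == "hyper" & at$region == "gene_body", ]
  expect_equal(bh$arm[which.min(bh$p)], "chr1q")
})

test_that("genome-wide region tests detect the planted functional asymmetry", {
  rr <- default_scenario()$report$region_ratios
  r <- rr$ratios
  get <- function(rg, st) r$ratio[r$region == rg & r$state == st]
  expect_gt(get("gene_body", "hyper"), get("promoter", "hyper"))
  expect_gt(get("enhancer", "hyper"), get("promoter", "hyper"))
  expect_gt(get("promoter", "hypo"), get("gene_body", "hypo"))
  expect_gt(get("promoter", "hypo"), get("enhancer", "hypo"))
  t <- rr$tests
  pb <- t[t$state == "hyper" & t$region_a == "promoter" & t$region_b == "gene_body", ]
  expect_lt(pb$p, 0.001)
  expect_lt(pb$t, 0)
})

test_that("paired region test flags a constant difference as degenerate", {
  tab <- expand.grid(arm = c("a1", "a2", "a3"),
                     region = c("promoter", "gene_body", "enhancer"),
                     state = c("hyper", "hypo"), stringsAsFactors = FALSE)
  tab$excluded <- FALSE
  tab$numerator <- 1L
  tab$denominator <- 10L
  # promoter = {1,2,3}/10, gene_body = {2,3,4}/10: constant difference
  tab$ratio <- 0.5
  tab$ratio[tab$region == "promoter" & tab$state == "hyper"] <- c(1, 2, 3) / 10
  tab$ratio[tab$region == "gene_body" & tab$state == "hyper"] <- c(2, 3, 4) / 10
  out <- genomewide_region_ratios(tab)
  row <- out$tests[out$tests$region_a == "promoter" &
                     out$tests$region_b == "gene_body" & out$tests$state == "hyper", ]
  expect_true(row$degenerate)
  expect_true(is.na(row$p))
  expect_equal(row$mean_diff, -0.1)
  # identical vectors: t = 0 is degenerate too (zero-variance difference)
  same <- out$tests[out$tests$region_a == "gene_body" &
                      out$tests$region_b == "enhancer" & out$tests$state == "hypo", ]
  expect_true(same$degenerate)
})

test_that("arm-vs-genome bootstrap test is seeded and Welch-based", {
  sc <- default_scenario()
  a1 <- arm_vs_genome_test(sc$report$common, sc$report$manifest, sc$ds$genome,
                           b = 50, seed = 5)
  a2 <- arm_vs_genome_test(sc$report$common, sc$report$manifest, sc$ds$genome,
                           b = 50, seed = 5)
  expect_identical(a1, a2)
  expect_true(all(a1$q >= a1$p | is.na(a1$q)))

  # Welch statistic against the textbook formula on fixed vectors
  x <- c(0.1, 0.2, 0.15, 0.3); y <- c(0.4, 0.35, 0.5)
  tt <- t.test(x, y, var.equal = FALSE)
  welch <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 3)
  expect_equal(unname(tt$statistic), welch, tolerance = 1e-12)
})

test_that("desert detection needs zero common calls plus adequate coverage", {
  sc <- default_scenario()
  des <- sc$report$deserts
  flagged <- paste(des$chrom[des$desert], des$band[des$desert], sep = ":")
  expect_setequal(flagged, synth_spec()$desert_bands)

  # coverage guard: a zero-coverage band is never a desert
  expect_true(all(des$coverage[des$desert] >= 50))
  zero_cov <- des[des$coverage == 0, ]
  if (nrow(zero_cov)) expect_false(any(zero_cov$desert))

  # monotone in min_probes: raising the threshold never adds a desert
  lo <- desert_bands(sc$report$common, sc$report$manifest, sc$ds$genome, min_probes = 10)
  hi <- desert_bands(sc$report$common, sc$report$manifest, sc$ds$genome, min_probes = 150)
  expect_true(all(!hi$desert | lo$desert))
})

test_that("track export clips sign-preserving and round-trips bedGraph", {
  g <- tiny_genome()
  man <- tiny_manifest(6)
  man$promoter <- TRUE; man$gene_body <- FALSE; man$enhancer <- FALSE
  man <- assign_arms(man, g)
  mean_m <- setNames(c(8.3, 2.0, 3.5, -8.3, -2.0, -1.95), man$probe_id)
  common <- list(hyper = man$probe_id[1:3], hypo = man$probe_id[4:6])
  dir <- tempfile()
  export_tracks(common, mean_m, man, g, dir)
  hyper <- read_bedgraph(file.path(dir, "common_hyper_promoter.bedGraph"))
  expect_equal(sort(hyper$value), sort(c(7.0, 2.0, 3.5)))  # 8.3 clipped to 7
  hypo <- read_bedgraph(file.path(dir, "common_hypo_promoter.bedGraph"))
  expect_equal(sort(hypo$value), sort(c(-7.0, -2.0, -1.95)))
  # 0-based half-open records
  expect_equal(hyper$end - hyper$start, rep(1L, 3))
  expect_equal(sort(hyper$start + 1), sort(man$position[1:3]))
  # round trip is exact
  f <- file.path(dir, "common_hyper_promoter.bedGraph")
  df <- read_bedgraph(f)
  write_bedgraph(df, f)
  expect_identical(read_bedgraph(f), df)
  bad <- man; bad$chromosome[1] <- "chrZ"
  expect_error(export_tracks(common, mean_m, bad, g, tempfile()), "chrZ")
})
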