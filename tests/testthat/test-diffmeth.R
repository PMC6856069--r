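make_m <- function(nprobe, groups, n_per, sd = 1, seed = 1, shift = NULL) {
  set.seed(seed)
  sheet <- data.frame(
    sample_id = paste0(rep(groups, each = n_per), "_", seq_len(n_per)),
    group = rep(groups, each = n_per), platform = "A450K",
    stringsAsFactors = FALSE)
  m <- matrix(rnorm(nprobe * nrow(sheet), 0, sd), nprobe, nrow(sheet),
              dimnames = list(sprintf("cg%04d", seq_len(nprobe)), sheet$sample_id))
  if (!is.null(shift))
    for (g in names(shift)) m[, sheet$group == g] <- m[, sheet$group == g] + shift[[g]]
  list(m = m, sheet = sheet)
}

test_that("group means equal the direct column means", {
  d <- make_m(30, c("a", "b"), 4)
  mu <- group_mean_m(d$m, d$sheet, "a")
  expect_equal(as.numeric(mu), unname(rowMeans(d$m[, d$sheet$group == "a"])),
               tolerance = 1e-12)
  one <- make_m(5, c("a", "b"), 1)
  expect_equal(as.numeric(group_mean_m(one$m, one$sheet, "a")),
               unname(one$m[, 1]))
  expect_error(group_mean_m(d$m, d$sheet, "zzz"), "no samples")
})

test_that("state calling partitions at inclusive +/-2 cutoffs", {
  mm <- c(a = 2.0, b = 0, c = -2.0, d = 1.999, e = -1.999, f = 5)
  st <- call_states(mm)
  expect_equal(st$state, c("hyper", "neither", "hypo", "neither", "neither", "hyper"))
  expect_error(call_states(mm, hyper_min = -2, hypo_max = 2), "exceed")
  # symmetry: negating M swaps hyper and hypo exactly
  flipped <- call_states(-mm)
  expect_equal(flipped$state == "hyper", st$state == "hypo")
  expect_equal(flipped$state == "hypo", st$state == "hyper")
})

test_that("per-probe Welch t matches t.test to 1e-12", {
  d <- make_m(50, c("a", "b"), 7, seed = 2, shift = list(a = 0.3))
  res <- welch_t_per_probe(d$m, d$sheet, "a", "b")
  for (i in c(1, 17, 50)) {
    tt <- t.test(d$m[i, d$sheet$group == "a"], d$m[i, d$sheet$group == "b"],
                 var.equal = FALSE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$df[i], unname(tt$parameter), tolerance = 1e-12)
  }
  # identical groups: t = 0; degenerate all-constant probes get p = 1
  m2 <- rbind(rep(c(1, 2, 3), 2), rep(4, 6))
  rownames(m2) <- c("x", "y")
  colnames(m2) <- paste0("s", 1:6)
  sh <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("a", "b"), each = 3), platform = "A450K")
  r2 <- welch_t_per_probe(m2, sh, "a", "b")
  expect_equal(r2$t[1], 0)
  expect_equal(r2$p[2], 1)
  expect_true(r2$degenerate[2])
})

test_that("Welch type-I error under the global null stays near alpha", {
  d <- make_m(2000, c("a", "b"), 10, seed = 99)
  res <- welch_t_per_probe(d$m, d$sheet, "a", "b")
  frac <- mean(res$p < 0.05)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), ci)
})

test_that("BH q-values match the hand example and the brute-force definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(8)
  for (i in 1:5) {
    p <- runif(40)^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 2)), "outside")
})

test_that("top-K selection is deterministic under heavy ties", {
  res <- data.frame(probe_id = c("c", "a", "b", "d"),
                    q = c(0.02, 0.01, 0.01, 0.02),
                    delta_m = c(1, 0.5, 2, -3))
  # q asc, then larger |delta|, then probe_id
  expect_equal(top_k_probes(res, 4), c("b", "a", "d", "c"))
  expect_equal(top_k_probes(res, 2), c("b", "a"))
  expect_error(top_k_probes(res, 0), "positive")
  expect_error(top_k_probes(res, 9), "exceeds")

  set.seed(13)
  tie <- data.frame(probe_id = sprintf("p%02d", 1:30),
                    q = sample(c(0.1, 0.2), 30, TRUE),
                    delta_m = sample(c(-1, 1, 2), 30, TRUE))
  ord <- with(tie, order(q, -abs(delta_m), probe_id))
  expect_equal(top_k_probes(tie, 30), tie$probe_id[ord])
})

test_that("hierarchical ordering keeps planted clusters contiguous", {
  # 1-D toy {0, 1, 10}: the near pair merges first
  m <- matrix(c(0, 1, 10), 1, 3, dimnames = list("p", c("s1", "s2", "s3")))
  h <- hierarchical_order(rbind(m, m))
  expect_equal(sort(h$sample_hclust$merge[1, ]), c(-2, -1))

  d <- make_m(100, c("a", "b"), 5, seed = 4, shift = list(a = 6))
  h2 <- hierarchical_order(d$m)
  grp <- d$sheet$group[h2$sample_order]
  expect_equal(length(rle(grp)$lengths), 2)  # each cluster contiguous

  # duplicate samples end up adjacent
  dup <- cbind(d$m, dup1 = d$m[, 1])
  h3 <- hierarchical_order(dup)
  ord <- h3$sample_order
  expect_equal(abs(which(ord == 1) - which(ord == ncol(dup))), 1)
  expect_warning(hierarchical_order(matrix(1, 3, 3)), "constant")
})

test_that("differential pipeline recovers planted two-group effects", {
  spec <- synth_spec(n_probes = 4000, groups = c("mutant", "wildtype"),
                     samples_per_group = 10, control_groups = "wildtype",
                     desert_bands = character(0))
  ds <- simulate_dataset(spec, seed = 21)
  m <- beta_to_m(ds$beta)
  res <- diff_methylation(m, ds$sheet, "mutant", "wildtype")
  truth_diff <- ds$truth$delta[, "mutant"] != 0
  sens <- mean(res$significant[truth_diff])
  spec_ <- mean(!res$significant[!truth_diff])
  expect_gte(sens, 0.95)
  expect_gte(spec_, 0.95)
  # direction of the planted shift is recovered
  up <- ds$truth$delta[, "mutant"] > 0
  expect_true(all(res$direction[res$significant & up] == "hyper_in_a"))

  # region counts follow the planted design: bodies/enhancers hyper,
  # promoters hypo, with multi-membership duplication
  rc <- region_direction_counts(res, ds$manifest)
  expect_gt(rc$hyper[rc$region == "gene_body"], rc$hyper[rc$region == "promoter"])
  expect_gt(rc$hyper[rc$region == "enhancer"], rc$hyper[rc$region == "promoter"])
  expect_gt(rc$hypo[rc$region == "promoter"], rc$hypo[rc$region == "gene_body"])
})

test_that("a probe in several regions is counted once per region", {
  man <- tiny_manifest(4)
  man$promoter <- c(TRUE, TRUE, FALSE, FALSE)
  man$gene_body <- c(TRUE, FALSE, TRUE, FALSE)
  man$enhancer <- c(TRUE, FALSE, FALSE, FALSE)
  res <- data.frame(probe_id = man$probe_id,
                    significant = c(TRUE, TRUE, TRUE, FALSE),
                    direction = c("hyper_in_a", "hypo_in_a", "hyper_in_a", "hyper_in_a"))
  rc <- region_direction_counts(res, man)
  expect_equal(rc$hyper, c(1L, 2L, 1L))
  expect_equal(rc$hypo, c(1L, 0L, 0L))
  empty <- region_direction_counts(res[res$probe_id == "none", ], man)
  expect_true(all(empty$hyper == 0) && all(empty$hypo == 0))
})
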