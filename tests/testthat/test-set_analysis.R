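random_collection <- function(n_groups = 6, universe = sprintf("cg%03d", 1:120),
                              seed = 1) {
  set.seed(seed)
  calls <- lapply(seq_len(n_groups), function(i) {
    mm <- runif(length(universe), -4, 4)
    names(mm) <- universe
    call_states(mm)
  })
  names(calls) <- paste0("g", seq_len(n_groups))
  make_state_sets(calls)
}

test_that("common probes are exactly those in the state in every group", {
  coll <- random_collection()
  for (st in c("hyper", "hypo")) {
    got <- common_probes(coll, st)
    sets <- coll[[st]]
    oracle <- Filter(function(p) all(vapply(sets, function(s) p %in% s, logical(1))),
                     unique(unlist(sets)))
    expect_setequal(got, oracle)
    for (s in sets) expect_true(all(got %in% s))
  }
  same <- make_state_sets(list(a = call_states(c(x = 3, y = -3)),
                               b = call_states(c(x = 3, y = -3))))
  expect_equal(common_probes(same, "hyper"), "x")
  empty <- make_state_sets(list(a = call_states(c(x = 3)),
                                b = call_states(c(x = 0))))
  expect_length(common_probes(empty, "hyper"), 0)
  expect_error(common_probes(coll, "lukewarm"))
})

test_that("unique probes equal the brute-force set difference", {
  coll <- random_collection(seed = 2)
  for (st in c("hyper", "hypo")) for (g in coll$groups) {
    got <- unique_probes(coll, g, st)
    others <- unlist(coll[[st]][setdiff(coll$groups, g)])
    expect_setequal(got, setdiff(coll[[st]][[g]], others))
    expect_true(all(got %in% coll[[st]][[g]]))
  }
  expect_error(unique_probes(coll, "nope", "hyper"), "unknown group")
  ident <- make_state_sets(list(a = call_states(c(x = 3)), b = call_states(c(x = 3))))
  expect_length(unique_probes(ident, "a", "hyper"), 0)
})

test_that("venn counts tally every membership pattern and conserve totals", {
  disj <- make_state_sets(list(a = call_states(c(x = 3, y = 0)),
                               b = call_states(c(x = 0, y = 3))))
  vc <- venn_counts(disj, "hyper")
  expect_equal(vc[["10"]], 1L)
  expect_equal(vc[["01"]], 1L)
  expect_equal(vc[["11"]], 0L)
  ident <- make_state_sets(list(a = call_states(c(x = 3, y = 3)),
                                b = call_states(c(x = 3, y = 3))))
  expect_equal(venn_counts(ident, "hyper")[["11"]], 2L)

  coll <- random_collection(n_groups = 4, seed = 3)
  vc4 <- venn_counts(coll, "hyper")
  expect_equal(sum(vc4), length(unique(unlist(coll$hyper))))
  # conservation: patterns containing group g sum to |set g|
  for (gi in 1:4) {
    has_g <- substr(names(vc4), gi, gi) == "1"
    expect_equal(sum(vc4[has_g]), length(coll$hyper[[gi]]))
  }
  # per-probe tally oracle
  uni <- unique(unlist(coll$hyper))
  pats <- vapply(uni, function(p)
    paste(as.integer(vapply(coll$hyper, function(s) p %in% s, logical(1))),
          collapse = ""), character(1))
  for (pt in names(vc4)) expect_equal(vc4[[pt]], sum(pats == pt))

  eight <- random_collection(n_groups = 8)
  expect_error(venn_counts(eight, "hyper"), "at most 7")
})

test_that("specificity arithmetic reproduces the published tumor table", {
  counts <- idh_tumor_probe_counts()
  st <- specificity_from_counts(counts)
  by_group <- st$by_group
  hy <- by_group[by_group$state == "hyper", ]
  expect_equal(hy$pct_unique[hy$group == "AML"], 8.0)
  expect_equal(hy$pct_unique[hy$group == "Astrocytoma"], 1.4)
  expect_equal(hy$pct_unique,
               c(8.0, 1.4, 3.0, 2.6, 5.5, 3.0))
  lo <- by_group[by_group$state == "hypo", ]
  expect_equal(lo$pct_unique, c(7.1, 1.1, 1.8, 3.0, 2.5, 3.2))
  av <- st$averages
  expect_equal(av$avg_total[av$state == "hyper"], 108516)
  expect_equal(av$avg_unique[av$state == "hyper"], 4386)
  expect_equal(av$avg_pct_unique[av$state == "hyper"], 3.9)
  expect_equal(av$avg_total[av$state == "hypo"], 96013)
  expect_equal(av$avg_unique[av$state == "hypo"], 2978.5)
  expect_equal(av$avg_pct_unique[av$state == "hypo"], 3.1)
})

test_that("percent rounding is half-up and degenerate totals are NA", {
  # 1752/100100 = 1.75025% must round to 1.8, not banker's 1.7
  one <- specificity_from_counts(
    data.frame(group = "g", state = "hypo", total = 100100, unique = 1752))
  expect_equal(one$by_group$pct_unique, 1.8)
  zero <- specificity_from_counts(
    data.frame(group = c("g", "h"), state = "hyper",
               total = c(0, 100), unique = c(0, 0)))
  expect_true(is.na(zero$by_group$pct_unique[1]))
  expect_equal(zero$by_group$pct_unique[2], 0.0)
  expect_error(specificity_from_counts(
    data.frame(group = "g", state = "hyper", total = 10, unique = 11)),
    "exceeds")
})

test_that("specificity_table agrees with per-set counting on a collection", {
  coll <- random_collection(seed = 9)
  st <- specificity_table(coll)
  hy <- st$by_group[st$by_group$state == "hyper", ]
  expect_equal(hy$total, unname(vapply(coll$hyper, length, integer(1))))
  expect_equal(hy$unique[1], length(unique_probes(coll, "g1", "hyper")))
})
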