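# Cross-tumor common/unique probe algebra and the specificity summary
# (totals, uniques, percent tumor-specific, column averages).

STATES <- c("hyper", "hypo")

#' Bundle per-group state calls into a state-set collection
#'
#' @param calls_by_group named list of [call_states()] data.frames, one per
#'   group, all over the same probe universe.
#' @return object of class `state_set_collection`: for each state, a named
#'   list of probe-id sets per group.
#' @export
make_state_sets <- function(calls_by_group) {
  if (is.null(names(calls_by_group)) || any(names(calls_by_group) == ""))
    stop2("calls_by_group must be a named list")
  sets <- lapply(STATES, function(st)
    lapply(calls_by_group, function(df) df$probe_id[df$state == st]))
  names(sets) <- STATES
  structure(list(groups = names(calls_by_group),
                 hyper = sets$hyper, hypo = sets$hypo),
            class = "state_set_collection")
}

#' @export
print.state_set_collection <- function(x, ...) {
  cat("state_set_collection over", length(x$groups), "groups:",
      paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

state_sets <- function(collection, state) {
  state <- match.arg(state, STATES)
  collection[[state]]
}

#' Probes in a methylation state in every group
#'
#' Intersection of the given state's probe sets across all groups — e.g. the
#' commonly hypermethylated probes shared by all tumor types.
#'
#' @param collection a [make_state_sets()] collection.
#' @param state `"hyper"` or `"hypo"`.
#' @return character vector of probe ids.
#' @export
common_probes <- function(collection, state) {
  sets <- state_sets(collection, state)
  if (length(sets) < 2) stop2("need >= 2 groups")
  Reduce(intersect, sets)
}

#' Probes in a methylation state in exactly one group
#'
#' Set difference of a group's state set against the union of every other
#' group's same-state set (tumor-type specific probes).
#'
#' @inheritParams common_probes
#' @param group the group whose unique probes are wanted.
#' @return character vector of probe ids.
#' @export
unique_probes <- function(collection, group, state) {
  sets <- state_sets(collection, state)
  if (!group %in% names(sets)) stop2("unknown group '", group, "'")
  setdiff(sets[[group]], unlist(sets[names(sets) != group], use.names = FALSE))
}

#' Venn membership-pattern counts
#'
#' Tallies every nonempty group-membership pattern of a state's probe sets
#' (the numbers behind a k-set Venn diagram). Patterns are bitstrings in
#' group order, `"101"` meaning present in groups 1 and 3 only.
#'
#' @inheritParams common_probes
#' @return named integer vector: pattern bitstring -> probe count (patterns
#'   with zero probes included; counts sum to the union size).
#' @export
venn_counts <- function(collection, state) {
  sets <- state_sets(collection, state)
  k <- length(sets)
  if (k > 7) stop2("venn_counts supports at most 7 groups")
  universe <- unique(unlist(sets, use.names = FALSE))
  all_pat <- vapply(seq_len(2^k - 1), function(i)
    paste(rev(as.integer(intToBits(i)[seq_len(k)])), collapse = ""), character(1))
  if (!length(universe))
    return(stats::setNames(integer(length(all_pat)), all_pat))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pat <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(factor(pat, levels = all_pat))
  stats::setNames(as.integer(counts), names(counts))
}

#' Specificity summary from per-group total and unique counts
#'
#' The arithmetic behind the tumor-specificity table: percent tumor-specific
#' probes (100 * unique / total, rounded half-up to one decimal) per group
#' and state, plus per-state column averages (totals rounded half-up to
#' integer, unique average unrounded, percent average half-up to one
#' decimal).
#'
#' @param counts data.frame with columns `group`, `state`, `total`, `unique`.
#' @return list of class `specificity_table` with `by_group` and `averages`
#'   data.frames.
#' @export
specificity_from_counts <- function(counts) {
  need <- setdiff(c("group", "state", "total", "unique"), names(counts))
  if (length(need)) stop2("counts missing column(s): ", paste(need, collapse = ", "))
  if (any(counts$unique > counts$total)) stop2("unique count exceeds total")
  pct_raw <- ifelse(counts$total == 0, NA_real_, 100 * counts$unique / counts$total)
  by_group <- data.frame(counts[c("group", "state", "total", "unique")],
                         pct_unique = round_half_up(pct_raw, 1),
                         stringsAsFactors = FALSE)
  averages <- do.call(rbind, lapply(split(seq_len(nrow(counts)), counts$state), function(i)
    data.frame(state = counts$state[i[1]],
               avg_total = round_half_up(mean(counts$total[i]), 0),
               avg_unique = mean(counts$unique[i]),
               avg_pct_unique = round_half_up(mean(pct_raw[i], na.rm = TRUE), 1),
               stringsAsFactors = FALSE)))
  rownames(averages) <- NULL
  structure(list(by_group = by_group, averages = averages),
            class = "specificity_table")
}

#' Specificity summary of a state-set collection
#'
#' Computes per-group totals and unique counts from the probe sets, then
#' summarises via [specificity_from_counts()].
#'
#' @inheritParams common_probes
#' @return a `specificity_table`.
#' @export
specificity_table <- function(collection) {
  counts <- do.call(rbind, lapply(STATES, function(st) {
    sets <- state_sets(collection, st)
    data.frame(group = names(sets), state = st,
               total = vapply(sets, length, integer(1)),
               unique = vapply(names(sets), function(g)
                 length(unique_probes(collection, g, st)), integer(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  specificity_from_counts(counts)
}

#' @export
print.specificity_table <- function(x, ...) {
  print(x$by_group); cat("\n"); print(x$averages)
  invisible(x)
}

#' Write specificity / Venn results to tab-separated text
#'
#' @param x a `specificity_table` or named Venn-count vector.
#' @param path output path.
#' @export
write_specificity_table <- function(x, path) {
  df <- x$by_group
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$averages, sub("(\\.[^.]+)?$", "_averages\\1", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_specificity_table
#' @export
write_venn_counts <- function(x, path) {
  utils::write.table(data.frame(pattern = names(x), count = as.integer(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
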