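#' Per-group medians
#'
#' @param values numeric vector (e.g. per-study powers).
#' @param labels group label per value (e.g. subfield).
#' @return Named numeric vector of group medians.
#' @export
group_medians <- function(values, labels) {
  if (length(values) != length(labels))
    stop_domain("`values` and `labels` must have equal length")
  if (length(values) == 0) stop_domain("no observations")
  med <- tapply(values, as.character(labels), stats::median)
  out <- as.numeric(med)
  names(out) <- names(med)
  out
}

# Kruskal-Wallis H from a vector of (precomputed) ranks and a group factor,
# with the usual tie correction. Ranks are computed once by the caller; under
# label permutation only the grouping changes, so permutations are cheap.
kw_stat <- function(ranks, group_idx, n_groups, tie_correction) {
  N <- length(ranks)
  R <- vapply(seq_len(n_groups), function(g) sum(ranks[group_idx == g]),
              numeric(1))
  n <- tabulate(group_idx, n_groups)
  h <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  h / tie_correction
}

#' Permutation test of group equivalence
#'
#' Tests whether several groups of values are exchangeable (drawn from a
#' common distribution) by permuting group labels. The observed statistic is
#' the Kruskal-Wallis H (rank-based, tie-corrected) — a K-group statistic
#' consistent with Mann-Whitney pairwise follow-ups; any exchangeable
#' statistic would be valid, and H is the package's documented choice. The
#' p-value uses the add-one convention
#' `p = (1 + #\{H_perm >= H_obs\}) / (1 + n_perm)`, so it can never fall
#' below `1 / (n_perm + 1)`.
#'
#' @inheritParams group_medians
#' @param n_perm number of label permutations (>= 99); default 9999.
#' @param seed RNG seed for the permutations.
#' @return An object of class `"power_group_test"`: `statistic` (observed
#'   H), `p_value`, `n_permutations`, `per_group_medians`.
#' @export
permutation_equivalence_test <- function(values, labels, n_perm = 9999,
                                         seed = NULL) {
  if (length(values) != length(labels))
    stop_domain("`values` and `labels` must have equal length")
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) stop_domain("need at least 2 groups")
  if (n_perm < 99) stop_domain("`n_perm` must be >= 99")
  group_idx <- match(labels, groups)
  n_groups <- length(groups)
  N <- length(values)
  ranks <- rank(values)
  ties <- table(values)
  tie_c <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_c <= 0) stop_domain("all values are tied; H is undefined")

  h_obs <- kw_stat(ranks, group_idx, n_groups, tie_c)
  h_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    kw_stat(ranks, sample(group_idx), n_groups, tie_c), numeric(1)))
  p <- (1 + sum(h_perm >= h_obs)) / (1 + n_perm)

  structure(list(statistic = h_obs, p_value = p,
                 n_permutations = as.integer(n_perm),
                 per_group_medians = group_medians(values, labels)),
            class = "power_group_test")
}

#' @export
print.power_group_test <- function(x, ...) {
  cat(sprintf("Permutation test of group equivalence (Kruskal-Wallis H)\n"))
  cat(sprintf("  H = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  cat("  group medians:\n")
  print(round(x$per_group_medians, 3))
  invisible(x)
}

#' Pairwise Mann-Whitney U tests against a reference group
#'
#' Compares the reference group with every other group by a two-sided
#' Mann-Whitney U test (normal approximation with tie correction, no
#' continuity correction). P-values are raw by default; set
#' `adjust = "holm"` for a Holm correction.
#'
#' @inheritParams group_medians
#' @param reference label of the reference group.
#' @param adjust multiplicity adjustment: `"none"` (default) or `"holm"`.
#' @return data.frame with one row per comparison: `group`, `U` (the
#'   Mann-Whitney statistic for reference vs group), `p`.
#' @export
pairwise_mannwhitney <- function(values, labels, reference,
                                 adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  labels <- as.character(labels)
  if (!reference %in% labels) stop_domain("reference group not present")
  others <- setdiff(unique(labels), reference)
  if (length(others) == 0) stop_domain("need at least one comparison group")
  ref <- values[labels == reference]
  res <- lapply(others, function(g) {
    y <- values[labels == g]
    if (length(ref) < 1 || length(y) < 1)
      stop_domain("groups must be non-empty")
    wt <- suppressWarnings(
      stats::wilcox.test(ref, y, exact = FALSE, correct = FALSE))
    data.frame(group = g, U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}
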