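# Positional Shannon entropy of alignments, rank-sum comparison between
# component families, and Robinson-Foulds congruence of component trees.
# High per-column entropy in the effector-bearing regions, contrasted with
# conserved housekeeping families, is the screening signal for rapidly
# diversifying conflict-system components.

#' Shannon entropy of one alignment column
#'
#' `H = -sum p_a log2 p_a` over the 20 standard residues; gaps (`-`, `.`)
#' and `X` are excluded from the frequencies. Entropy is in bits, bounded
#' by `log2(20)`.
#'
#' @param column Character vector of single residues (one per row).
#' @return Entropy in bits, or `NA` for a column with no scorable residue.
#' @export
column_entropy <- function(column) {
  stopifnot(length(column) >= 1)
  res <- toupper(column)
  res <- res[!res %in% c("-", ".", "X")]
  if (!length(res)) return(NA_real_)
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

#' Mean positional entropy of an alignment
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` (default 0.5) are
#' skipped, following common practice for domain alignments where sparse
#' columns carry little signal; the profile reports how many columns were
#' used and skipped.
#'
#' @param msa An [msa()] object.
#' @param max_gap_fraction Columns with a larger gap fraction are skipped.
#' @param label Optional component label carried in the profile.
#' @return Object of class `entropy_profile`: list with `entropy`
#'   (per used column, bits), `mean_entropy`, `n_columns_used`,
#'   `n_columns_skipped`, `label`.
#' @export
mean_positional_entropy <- function(msa, max_gap_fraction = 0.5,
                                    label = NA_character_) {
  stopifnot(inherits(msa, "msa"), length(msa$rows) >= 2)
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  use <- gap_frac <= max_gap_fraction
  H <- apply(mat[, use, drop = FALSE], 2, column_entropy)
  H <- H[!is.na(H)]
  if (!length(H)) stop("no usable columns after gap filtering")
  structure(list(entropy = unname(H), mean_entropy = mean(H),
                 n_columns_used = length(H),
                 n_columns_skipped = ncol(mat) - length(H),
                 label = label),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("<entropy_profile>", if (!is.na(x$label)) x$label else "",
      sprintf("mean %.3f bits over %d columns (%d skipped)\n",
              x$mean_entropy, x$n_columns_used, x$n_columns_skipped))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two entropy samples
#'
#' Exact two-sided p-value when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. When every value in both groups is identical
#' the test is uninformative and p = 1 is returned.
#'
#' @param a,b Numeric vectors (each length >= 1).
#' @return List with `U` (Mann-Whitney statistic for `a`), `p`, `method`.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1,
                method = "degenerate"))
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p = min(1, p),
       method = if (exact) "exact" else "normal-approximation")
}

#' Robinson-Foulds congruence between two trees
#'
#' Both trees are pruned to their shared leaves and unrooted; the RF
#' distance is the size of the symmetric difference of non-trivial
#' bipartitions, normalized by `2 * (n_shared - 3)`, its maximum for
#' unrooted binary trees (0 = identical topology, 1 = no shared splits).
#'
#' @param tree_a,tree_b [ape::phylo] trees.
#' @return List with `n_shared`, `rf`, `rf_normalized`.
#' @export
rf_congruence <- function(tree_a, tree_b) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 4)
    stop("need at least 4 shared leaves, found ", length(shared))
  ta <- ape::unroot(ape::keep.tip(tree_a, shared))
  tb <- ape::unroot(ape::keep.tip(tree_b, shared))
  rf <- as.numeric(phangorn::RF.dist(ta, tb, normalize = FALSE))
  list(n_shared = length(shared), rf = rf,
       rf_normalized = rf / (2 * (length(shared) - 3)))
}
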