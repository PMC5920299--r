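## ---------------------------------------------------------------------------
## Posterior-comparison diagnostics based on bipartition (split) frequencies.
## ---------------------------------------------------------------------------

#' Split frequencies of a (possibly weighted) tree sample
#'
#' @param trees list of canonical `phylo` on one taxon set.
#' @param weights optional per-tree weights (normalized internally);
#'   `NULL` means equal weights.
#' @return named numeric vector: non-trivial split key -> frequency in
#'   `[0, 1]`.
#' @export
split_frequencies <- function(trees, weights = NULL) {
  if (length(trees) == 0L) return(numeric(0))
  taxsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(taxsets, identical, logical(1), y = taxsets[[1L]])))
    stop("trees are not all on the same taxon set")
  if (is.null(weights)) weights <- rep(1, length(trees))
  stopifnot(length(weights) == length(trees))
  w <- weights / sum(weights)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    ss <- splits(trees[[i]], include_trivial = FALSE)
    for (k in unique(ss$key)) {
      prev <- acc[[k]]
      acc[[k]] <- if (is.null(prev)) w[i] else prev + w[i]
    }
  }
  keys <- ls(acc)
  stats::setNames(vapply(keys, function(k) acc[[k]], numeric(1)), keys)
}

#' Absolute differences between two split-frequency tables
#'
#' Taken over the union of splits; a split absent from one table counts as
#' frequency 0 there.
#'
#' @param table_a,table_b named frequency vectors from [split_frequencies()].
#' @return list with `diffs` (named per-split `|delta f|`), `mean`, `sd`.
#' @export
split_abs_diff <- function(table_a, table_b) {
  keys <- union(names(table_a), names(table_b))
  fa <- ifelse(keys %in% names(table_a), table_a[keys], 0)
  fb <- ifelse(keys %in% names(table_b), table_b[keys], 0)
  d <- abs(fa - fb)
  names(d) <- keys
  list(diffs = d,
       mean = if (length(d)) mean(d) else 0,
       sd = if (length(d) > 1L) stats::sd(d) else 0)
}

#' Average standard deviation of split frequencies (ASDSF) between two runs
#'
#' Over all splits whose frequency reaches `min_freq` in at least one run,
#' the mean of the two-run sample standard deviation (n-1 denominator, the
#' MrBayes convention) of the split frequency.  0 indicates identical split
#' distributions; below 0.01 is the conventional convergence criterion.
#'
#' @param trees_a,trees_b the two tree samples (lists of `phylo`).
#' @param weights_a,weights_b optional per-tree weights.
#' @param min_freq inclusion threshold (default 0.1).
#' @return the ASDSF value.
#' @export
asdsf <- function(trees_a, trees_b, weights_a = NULL, weights_b = NULL,
                  min_freq = 0.1) {
  ta <- split_frequencies(trees_a, weights_a)
  tb <- split_frequencies(trees_b, weights_b)
  keys <- union(names(ta), names(tb))
  fa <- ifelse(keys %in% names(ta), ta[keys], 0)
  fb <- ifelse(keys %in% names(tb), tb[keys], 0)
  keep <- pmax(fa, fb) >= min_freq
  if (!any(keep)) {
    warning("no splits reach min_freq = ", min_freq, "; ASDSF defined as 0")
    return(0)
  }
  mean(abs(fa[keep] - fb[keep]) / sqrt(2))   # 2-sample sd, n-1 denominator
}

#' Weighted Robinson-Foulds (L1) distance between two trees
#'
#' Sum over the union of splits (including trivial pendant splits) of the
#' absolute branch-length difference, with length 0 for splits absent from
#' a tree.
#'
#' @param tree_a,tree_b canonical `phylo` on the same taxon set.
#' @return the L1 branch-score distance.
#' @export
weighted_rf <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees are on different taxon sets")
  sa <- splits(tree_a, include_trivial = TRUE)
  sb <- splits(tree_b, include_trivial = TRUE)
  la <- tapply(sa$length, sa$key, sum)
  lb <- tapply(sb$length, sb$key, sum)
  keys <- union(names(la), names(lb))
  va <- ifelse(keys %in% names(la), la[keys], 0)
  vb <- ifelse(keys %in% names(lb), lb[keys], 0)
  sum(abs(va - vb))
}
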