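## ---------------------------------------------------------------------------
## Fitch parsimony (first pass only) and parsimony-based attachment weights.
## ---------------------------------------------------------------------------

#' Fitch parsimony score of a tree
#'
#' First-pass Fitch count of the minimum number of state changes, summed over
#' sites.  Ambiguity codes contribute their state set; gaps and `?` the full
#' set.  The score is invariant to the traversal root.
#'
#' @param tree a canonical `phylo`.
#' @param aln alignment covering the tree's leaves.
#' @return the (integer-valued) parsimony score.
#' @export
fitch_score <- function(tree, aln) {
  sd <- make_site_data(aln, tree$tip.label)
  cpp_fitch(tree$edge, length(tree$tip.label), sd$states, sd$weights)
}

#' Parsimony score of every candidate attachment branch
#'
#' `s_i` is the Fitch score of the tree with the new taxon attached to branch
#' `i` (the position along the branch is irrelevant to parsimony).  Computed
#' with shared per-subtree state-set caches; equal to naively re-scoring each
#' attached tree.
#'
#' @inheritParams fitch_score
#' @param new_taxon name of the sequence to attach.
#' @return numeric vector of length `2n - 3` in [enumerate_edges()] order.
#' @export
attachment_parsimony_scores <- function(tree, aln, new_taxon) {
  if (new_taxon %in% tree$tip.label)
    stop("taxon '", new_taxon, "' is already in the tree")
  taxa <- c(tree$tip.label, new_taxon)
  sd <- make_site_data(aln, taxa)
  ntip <- length(tree$tip.label)
  cpp_fitch_attach(tree$edge, ntip, sd$states[seq_len(ntip), , drop = FALSE],
                   sd$weights, sd$states[ntip + 1L, ])
}

#' Multinomial attachment weights from parsimony scores
#'
#' The unnormalized weight of branch `i` is `exp(min(S) - s_i)`, so the best
#' (lowest) score gets weight 1 and each extra change costs a factor `e`.
#'
#' @param S vector of per-branch parsimony scores.
#' @return normalized probability vector (sums to 1).
#' @export
parsimony_weights <- function(S) {
  if (length(S) == 0L) stop("empty score vector")
  g <- exp(min(S) - S)
  g / sum(g)
}
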