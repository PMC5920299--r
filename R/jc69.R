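## ---------------------------------------------------------------------------
## Phylogenetic likelihood under JC69 via Felsenstein pruning, with analytic
## first/second derivatives in single branch lengths and fast attachment
## evaluations that reuse inside/outside partial caches.
## ---------------------------------------------------------------------------

#' JC69 transition probability
#'
#' `p_same(t) = 1/4 + (3/4) exp(-4t/3)`, `p_diff(t) = 1/4 - (1/4) exp(-4t/3)`.
#'
#' @param same_state logical; probability of observing the same state (TRUE)
#'   or one particular different state (FALSE).
#' @param t branch length in expected substitutions per site, `>= 0`.
#' @return transition probability (vectorized over `t`).
#' @export
jc69_transition_prob <- function(same_state, t) {
  if (any(t < 0)) stop("branch length must be >= 0")
  e <- exp(-4 * t / 3)
  if (same_state) 0.25 + 0.75 * e else 0.25 - 0.25 * e
}

## tipstate rows must be ordered as tree$tip.label
tree_site_data <- function(tree, aln) {
  make_site_data(aln, tree$tip.label)
}

#' Log-likelihood of an alignment on a tree under JC69
#'
#' Felsenstein pruning with per-site log-scale accumulators; 1/4 stationary
#' frequencies at the (arbitrary) root.  Gaps, `?` and IUPAC ambiguity codes
#' are treated as partial/missing observations.
#'
#' @param tree a canonical `phylo`.
#' @param aln named character vector of aligned sequences covering all leaf
#'   labels.
#' @return the log-likelihood (a finite negative number for real data).
#' @export
log_likelihood <- function(tree, aln) {
  sd <- tree_site_data(tree, aln)
  cpp_loglik(tree$edge, tree$edge.length, length(tree$tip.label),
             sd$states, sd$weights)
}

## Attachment context: everything needed to evaluate the likelihood of the
## tree with `new_taxon` attached anywhere, many times, cheaply.  Patterns
## are compressed over the union taxon set so the new sequence shares them.
attach_ctx <- function(tree, aln, new_taxon) {
  if (new_taxon %in% tree$tip.label)
    stop("taxon '", new_taxon, "' is already in the tree")
  taxa <- c(tree$tip.label, new_taxon)
  sd <- make_site_data(aln, taxa)
  ntip <- length(tree$tip.label)
  states <- sd$states[seq_len(ntip), , drop = FALSE]
  arr <- cpp_edge_arrays(tree$edge, tree$edge.length, ntip, states)
  list(tree = tree, ntip = ntip, new_taxon = new_taxon,
       newstate = sd$states[ntip + 1L, ], weights = sd$weights,
       states_tree = states,
       elen = tree$edge.length, arrays = arr,
       slices = new.env(parent = emptyenv()),
       base_loglik = cpp_loglik(tree$edge, tree$edge.length, ntip,
                                states, sd$weights))
}

## per-edge views of the inside/outside arrays, sliced once and memoized
ctx_slice <- function(ctx, edge) {
  key <- as.character(edge)
  sl <- ctx$slices[[key]]
  if (is.null(sl)) {
    P <- length(ctx$weights)
    i0 <- (edge - 1L) * P * 4L
    j0 <- (edge - 1L) * P
    sl <- list(D = ctx$arrays$D[i0 + seq_len(4L * P)],
               Ds = ctx$arrays$Dscale[j0 + seq_len(P)],
               U = ctx$arrays$U[i0 + seq_len(4L * P)],
               Us = ctx$arrays$Uscale[j0 + seq_len(P)])
    ctx$slices[[key]] <- sl
  }
  sl
}

## Fast attachment evaluation from a context.  Returns the 5-vector
## (ll, d/dx, d2/dx2, d/dy, d2/dy2); derivatives only when derivs = TRUE.
ctx_attach <- function(ctx, edge, x, y, derivs = FALSE) {
  sl <- ctx_slice(ctx, edge)
  cpp_attach_loglik(sl$D, sl$Ds, sl$U, sl$Us,
                    ctx$weights, ctx$newstate,
                    ctx$elen[edge], x, y, derivs)
}

#' Log-likelihood of a tree with a new taxon attached
#'
#' Equals `log_likelihood(attach_taxon(tree, edge, x, y, new_taxon), aln)`
#' but reuses cached inside/outside partial likelihoods toward the
#' attachment branch instead of re-running pruning on the full tree.
#'
#' @inheritParams attach_taxon
#' @param aln alignment covering the tree's leaves and the new taxon.
#' @param new_taxon name of the sequence to attach.
#' @param edge attachment branch index.
#' @param x distal length in `[0, |e|]`.
#' @param y pendant branch length.
#' @return log-likelihood of the augmented tree.
#' @export
attachment_loglik <- function(tree, aln, new_taxon, edge, x, y) {
  ctx <- attach_ctx(tree, aln, new_taxon)
  ctx_attach(ctx, edge, x, y)[1L]
}

## Coordinate-wise Brent optimization of (x, y) for one attachment branch.
ctx_optimize <- function(ctx, edge, tol = 1e-8, max_rounds = 20L) {
  le <- ctx$elen[edge]
  med <- stats::median(ctx$elen)
  ymax <- 20 * med + 1
  fy <- function(y, x) ctx_attach(ctx, edge, x, y)[1L]
  fx <- function(x, y) ctx_attach(ctx, edge, x, y)[1L]
  x <- if (le > 1e-8) le / 2 else 0
  y <- max(med, 1e-4)
  ll <- ctx_attach(ctx, edge, x, y)[1L]
  for (r in seq_len(max_rounds)) {
    if (le > 1e-8) {
      ox <- stats::optimize(fx, interval = c(0, le), y = y,
                            maximum = TRUE, tol = min(tol, le / 4))
      x <- ox$maximum
    }
    oy <- stats::optimize(fy, interval = c(1e-9, ymax), x = x,
                          maximum = TRUE, tol = tol)
    y <- oy$maximum
    ## Brent never quite reaches the boundary; snap if it improves
    ll_new <- oy$objective
    for (cand in list(c(0, y), c(le, y))) {
      if (le > 1e-8) {
        v <- ctx_attach(ctx, edge, cand[1L], cand[2L])[1L]
        if (v > ll_new + 1e-12) { x <- cand[1L]; ll_new <- v }
      }
    }
    y0 <- ctx_attach(ctx, edge, x, 0)[1L]
    if (y0 > ll_new + 1e-12) { y <- 0; ll_new <- y0 }
    if (ll_new - ll < 1e-6 && r > 1L) { ll <- ll_new; break }
    ll <- ll_new
  }
  d <- ctx_attach(ctx, edge, x, y, derivs = TRUE)
  list(x_mle = x, y_mle = y, loglik = ll,
       info_x = -d[3L], d2_y = d[5L])
}

#' Jointly optimize the attachment position and pendant length on one branch
#'
#' Coordinate-wise Brent line searches on the distal length `x` and the
#' pendant length `y`, alternated until the joint log-likelihood improvement
#' drops below 1e-6 (at most 20 rounds).  The observed information
#' `I(x_MLE) = -d2/dx2 logL` comes from the analytic second derivative of the
#' pruning likelihood.  Branches shorter than 1e-8 pin `x = 0` and optimize
#' `y` only.
#'
#' @inheritParams attachment_loglik
#' @return list with `x_mle`, `y_mle`, `loglik`, `info_x` (observed
#'   information in `x` at the optimum) and `d2_y` (second derivative in `y`).
#' @export
optimize_attachment <- function(tree, aln, new_taxon, edge) {
  ctx <- attach_ctx(tree, aln, new_taxon)
  ctx_optimize(ctx, edge)
}
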