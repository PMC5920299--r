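## ---------------------------------------------------------------------------
## Reference Metropolis-Hastings sampler over (topology, branch lengths),
## targeting the same unnormalized posterior as the SMC engine.  Used to
## produce initial posterior tree samples and independent full-data
## references for the split diagnostics.  Moves: NNI topology swaps, a
## branch-length multiplier, and leaf SPR (prune a leaf, regraft uniformly).
## ---------------------------------------------------------------------------

#' Reference MCMC configuration
#'
#' @param iterations total Metropolis-Hastings iterations (default 300000).
#' @param thin_to number of evenly spaced samples recorded (default 1000).
#' @param burnin number of initial recorded samples discarded (default 250,
#'   i.e. 750 trees retained at the defaults).
#' @param prior_rate exponential branch-length prior rate (default 10).
#' @param move_weights proposal mix: NNI, branch multiplier, leaf SPR.
#' @param mult_lambda multiplier tuning constant (log-scale window width).
#' @param likelihood set `FALSE` to sample from the prior only (validation).
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 300000L, thin_to = 1000L, burnin = 250L,
                        prior_rate = 10,
                        move_weights = c(nni = 0.4, mult = 0.5, spr = 0.1),
                        mult_lambda = 2, likelihood = TRUE) {
  stopifnot(iterations > 0L, burnin < thin_to)
  structure(list(iterations = as.integer(iterations),
                 thin_to = as.integer(thin_to), burnin = as.integer(burnin),
                 prior_rate = prior_rate, move_weights = move_weights,
                 mult_lambda = mult_lambda, likelihood = likelihood),
            class = "mcmc_config")
}

## one NNI rearrangement across a uniformly chosen internal edge; symmetric
propose_nni <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2L] > ntip)
  if (length(internal) == 0L) return(NULL)
  i <- internal[sample.int(length(internal), 1L)]
  p <- tree$edge[i, 1L]; cc <- tree$edge[i, 2L]
  rows_c <- which(tree$edge[, 1L] == cc)
  rows_p <- setdiff(which(tree$edge[, 1L] == p), i)
  ra <- rows_c[sample.int(length(rows_c), 1L)]
  rx <- rows_p[sample.int(length(rows_p), 1L)]
  edge <- tree$edge
  edge[ra, 1L] <- p
  edge[rx, 1L] <- cc
  tr <- tree
  tr$edge <- edge
  attr(tr, "order") <- NULL
  list(tree = ape::reorder.phylo(tr, "postorder"), log_hastings = 0)
}

## leaf SPR: prune a random leaf (merging its two flanking branches) and
## regraft it uniformly on a branch of the reduced tree at a uniform
## position, keeping its pendant length
propose_leaf_spr <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(NULL)
  leaf <- tree$tip.label[sample.int(ntip, 1L)]
  det <- detach_taxon(tree, leaf)
  ne <- nrow(det$tree$edge)
  e <- sample.int(ne, 1L)
  le <- det$tree$edge.length[e]
  x <- stats::runif(1L, 0, le)
  newt <- attach_taxon(det$tree, e, x, det$pendant_length, leaf)
  list(tree = newt, log_hastings = log(le) - log(det$merged_length))
}

#' Sample phylogenetic trees by Metropolis-Hastings
#'
#' Runs the reference sampler on an alignment and returns the thinned,
#' post-burn-in tree sample (by default 750 trees), reader-compatible with
#' [init_particles()].
#'
#' @param aln named character vector of aligned sequences (all are used).
#' @param config an [mcmc_config()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param init optional starting tree (canonical `phylo`); default random
#'   topology with prior-drawn branch lengths.
#' @return list with `trees` (retained sample), `log_post` (trace at the
#'   recorded points), `acceptance` (per-move rates).
#' @export
mcmc_sample <- function(aln, config = mcmc_config(), seed = NULL,
                        init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- names(aln)
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 sequences")
  rate <- config$prior_rate
  tree <- if (is.null(init)) {
    topo <- ape::rtopology(n, rooted = FALSE, tip.label = taxa)
    topo$edge.length <- stats::rexp(nrow(topo$edge), rate)
    canonical_tree(topo)
  } else canonical_tree(init)
  sdat <- make_site_data(aln, taxa)
  states_for <- function(tr) sdat$states[match(tr$tip.label, taxa), , drop = FALSE]
  loglik <- function(tr) {
    if (!config$likelihood) return(0)
    cpp_loglik(tr$edge, tr$edge.length, n, states_for(tr), sdat$weights)
  }
  logprior <- function(tr) sum(stats::dexp(tr$edge.length, rate, log = TRUE))
  lp <- loglik(tree) + logprior(tree)
  mw <- config$move_weights / sum(config$move_weights)
  if (n == 3L) mw <- c(nni = 0, mult = 1, spr = 0)  # single topology
  rec_at <- unique(round(seq(1, config$iterations, length.out = config$thin_to)))
  trees <- vector("list", length(rec_at))
  lptrace <- numeric(length(rec_at))
  ri <- 1L
  prop_n <- c(nni = 0, mult = 0, spr = 0)
  acc_n <- c(nni = 0, mult = 0, spr = 0)
  for (it in seq_len(config$iterations)) {
    mv <- sample(c("nni", "mult", "spr"), 1L, prob = mw)
    prop_n[mv] <- prop_n[mv] + 1
    if (mv == "mult") {
      i <- sample.int(nrow(tree$edge), 1L)
      fac <- exp(config$mult_lambda * (stats::runif(1L) - 0.5))
      cand <- tree
      cand$edge.length[i] <- cand$edge.length[i] * fac
      lh <- log(fac)
    } else {
      pr <- if (mv == "nni") propose_nni(tree) else propose_leaf_spr(tree)
      if (is.null(pr)) next
      cand <- pr$tree
      lh <- pr$log_hastings
    }
    lp_cand <- loglik(cand) + logprior(cand)
    if (log(stats::runif(1L)) < lp_cand - lp + lh) {
      tree <- cand
      lp <- lp_cand
      acc_n[mv] <- acc_n[mv] + 1
    }
    if (ri <= length(rec_at) && it == rec_at[ri]) {
      trees[[ri]] <- tree
      lptrace[ri] <- lp
      ri <- ri + 1L
    }
  }
  acc <- ifelse(prop_n > 0, acc_n / prop_n, NA)
  overall <- sum(acc_n) / sum(prop_n)
  if (is.finite(overall) && (overall < 0.05 || overall > 0.8))
    warning("overall acceptance rate ", round(overall, 3),
            " outside [0.05, 0.8]; consider retuning moves")
  keep <- (config$burnin + 1L):length(trees)
  list(trees = trees[keep], log_post = lptrace[keep], acceptance = acc)
}
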