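## ---------------------------------------------------------------------------
## The online SMC loop: particles are whole unrooted trees; each generation
## grafts one new taxon onto every particle via a proposal kernel, reweights
## by the unnormalized-posterior ratio over the proposal density, and
## resamples (stratified) when the effective sample size drops.
## ---------------------------------------------------------------------------

#' Unnormalized log posterior of a tree
#'
#' Log-likelihood plus the exponential branch-length log prior summed over
#' branches.  The uniform-topology prior constant is particle-independent
#' within a generation and is omitted.
#'
#' @param tree a canonical `phylo`.
#' @param aln alignment covering the tree's leaves.
#' @param prior_rate exponential branch-length prior rate (default 10).
#' @return `log P(data | tree) + sum_b log dexp(l_b; rate)`.
#' @export
unnormalized_log_posterior <- function(tree, aln, prior_rate = 10) {
  log_likelihood(tree, aln) +
    sum(stats::dexp(tree$edge.length, prior_rate, log = TRUE))
}

#' Effective sample size of a weight vector
#'
#' `ESS = (sum w)^2 / sum(w^2)`; lies in `[1, K]` for K nonzero weights.
#'
#' @param weights nonnegative weights (need not be normalized).
#' @return the effective sample size.
#' @export
ess <- function(weights) {
  if (any(weights < 0)) stop("negative weight")
  s <- sum(weights)
  if (s == 0) stop("weight collapse: all weights are zero")
  s^2 / sum(weights^2)
}

#' Stratified resampling
#'
#' Inverts one uniform draw per stratum `((k-1)/K, k/K]` through the
#' cumulative weights; the expected copy count of particle `i` is
#' `K * w_i`, with lower variance than multinomial resampling.
#'
#' @param weights normalized weights.
#' @param k_out number of indices to draw (default `length(weights)`).
#' @return integer vector of `k_out` particle indices.
#' @export
stratified_resample <- function(weights, k_out = length(weights)) {
  w <- weights / sum(weights)
  u <- (seq_len(k_out) - 1 + stats::runif(k_out)) / k_out
  findInterval(u, cumsum(w), left.open = TRUE) + 1L
}

#' Initialize an SMC particle system from a posterior tree sample
#'
#' Each input tree is replicated `particle_factor` times with equal weights;
#' cached unnormalized log posteriors are computed once per input tree.
#'
#' @param trees list of canonical `phylo` on a common taxon set.
#' @param particle_factor integer `>= 1`; `K = particle_factor * length(trees)`.
#' @param aln alignment covering the trees' leaves.
#' @param config an [opsmc_config()].
#' @return a `particle_system` list: `trees` (per particle), `weights`
#'   (normalized), `log_post`, `tree_id` (distinct-tree index, for
#'   path-degeneracy caching), `generation`, `ess_trace`, `log_z` (running
#'   log normalizing-constant increments).
#' @export
init_particles <- function(trees, particle_factor, aln,
                           config = opsmc_config()) {
  stopifnot(particle_factor >= 1L, length(trees) >= 1L)
  taxsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(taxsets, identical, logical(1), y = taxsets[[1L]])))
    stop("initial trees are not all on the same taxon set")
  lp <- vapply(trees, unnormalized_log_posterior, numeric(1),
               aln = aln, prior_rate = config$prior_rate)
  K <- particle_factor * length(trees)
  id <- rep(seq_along(trees), each = particle_factor)
  structure(list(trees = trees[id], weights = rep(1 / K, K),
                 log_post = lp[id], tree_id = id,
                 generation = 0L, ess_trace = numeric(0),
                 log_z = numeric(0)),
            class = "particle_system")
}

#' One SMC generation: resample if needed, mutate, reweight
#'
#' If `ESS < resample_threshold * K`, particles are first resampled
#' (stratified) to equal weights.  Every particle then receives one
#' attachment draw of `new_taxon` from the kernel, and its unnormalized
#' weight is updated by
#' `w * exp(log pi_{n+1}(t') - log pi_n(t) - log Q(t -> t'))`.
#' The reported ESS is that of the new normalized weights, before any
#' resampling in the following generation.  Step 1 distributions and
#' per-edge attachment MLEs are cached per distinct input tree (path
#' degeneracy makes many particles share a tree).
#'
#' @param system a `particle_system`.
#' @param aln alignment covering current leaves and the new taxon.
#' @param new_taxon name of the sequence to insert.
#' @param kernel kernel code string or [parse_kernel()] result.
#' @param config an [opsmc_config()].
#' @return the updated `particle_system`.
#' @export
smc_step <- function(system, aln, new_taxon, kernel,
                     config = opsmc_config()) {
  if (is.character(kernel)) kernel <- parse_kernel(kernel, config$alpha)
  K <- length(system$trees)
  w <- system$weights
  ## (i) optional resampling on the previous generation's weights
  if (ess(w) < config$resample_threshold * K) {
    idx <- stratified_resample(w, K)
    system$trees <- system$trees[idx]
    system$log_post <- system$log_post[idx]
    system$tree_id <- system$tree_id[idx]
    w <- rep(1 / K, K)
  }
  ## (ii) mutation: one attachment draw per particle, with per-distinct-tree
  ## caches for contexts, Step 1 distributions and attachment MLEs
  ids <- system$tree_id
  ctxs <- new.env(parent = emptyenv())
  caches <- new.env(parent = emptyenv())
  log_inc <- numeric(K)
  new_trees <- vector("list", K)
  new_lp <- numeric(K)
  for (i in seq_len(K)) {
    key <- as.character(ids[i])
    ctx <- ctxs[[key]]
    if (is.null(ctx)) {
      ctx <- attach_ctx(system$trees[[i]], aln, new_taxon)
      ctxs[[key]] <- ctx
      caches[[key]] <- new.env(parent = emptyenv())
    }
    draw <- propose_ctx(ctx, kernel, config, caches[[key]])
    tr <- attach_taxon(system$trees[[i]], draw$edge, draw$x, draw$y, new_taxon)
    lp <- draw$loglik +
      sum(stats::dexp(tr$edge.length, config$prior_rate, log = TRUE))
    new_trees[[i]] <- tr
    new_lp[i] <- lp
    log_inc[i] <- lp - system$log_post[i] - draw$log_q
  }
  ## (iii) reweight
  lw <- log(w) + log_inc
  if (all(!is.finite(lw)))
    stop("weight collapse: all particle weights are -Inf at generation ",
         system$generation + 1L)
  lse <- logsumexp(lw)
  wn <- exp(lw - lse)
  system$trees <- new_trees
  system$log_post <- new_lp
  system$weights <- wn
  system$tree_id <- seq_len(K)   # all particles now distinct lineages
  system$generation <- system$generation + 1L
  system$ess_trace <- c(system$ess_trace, ess(wn))
  system$log_z <- c(system$log_z, lse - log(K))
  system
}

#' Run the full online SMC over a sequence of arriving taxa
#'
#' One [smc_step()] per new taxon, in the given order; deterministic given
#' `seed`.
#'
#' @param trees initial posterior tree sample (list of canonical `phylo`).
#' @param aln alignment covering all initial leaves and all new taxa.
#' @param new_taxa character vector of taxa to insert, in arrival order.
#' @param kernel kernel code string.
#' @param particle_factor particles per initial tree.
#' @param config an [opsmc_config()]; `median_ref`, when unset, is frozen to
#'   the median branch length of the first initial tree.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return the final `particle_system` (with `ess_trace` and `log_z` per
#'   generation).
#' @export
run_online <- function(trees, aln, new_taxa, kernel, particle_factor = 1L,
                       config = opsmc_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config$median_ref))
    config$median_ref <- stats::median(trees[[1L]]$edge.length)
  system <- init_particles(trees, particle_factor, aln, config)
  for (tx in new_taxa)
    system <- smc_step(system, aln, tx, kernel, config)
  system
}

#' Posterior expectation of a test function over the particle system
#'
#' @param system a `particle_system`.
#' @param phi function of a tree returning a scalar.
#' @return `sum_i w_i phi(t_i)`.
#' @export
posterior_expectation <- function(system, phi) {
  sum(system$weights * vapply(system$trees, phi, numeric(1)))
}
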