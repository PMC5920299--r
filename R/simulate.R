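## ---------------------------------------------------------------------------
## Benchmark simulator: birth-death trees, JC69 sequence evolution, and
## held-out taxa for online insertion.
## ---------------------------------------------------------------------------

#' Simulate a birth-death tree conditioned on a number of extant tips
#'
#' Forward simulation from a single lineage with exponential waiting times
#' (total event rate `k(lambda + mu)` for `k` extant lineages); the process
#' stops the first time `n` lineages are simultaneously extant, extinct
#' subtrees are pruned, and runs that die out before reaching `n` are
#' retried.  The resulting tree is ultrametric in time; branch lengths are
#' then rescaled so the median branch length equals `median_branch` expected
#' substitutions per site (`NULL` keeps raw time units).
#'
#' @param n number of extant tips (`>= 3`).
#' @param birth speciation rate lambda (default 6).
#' @param death extinction rate mu (default 2; must be `< birth`).
#' @param median_branch target median branch length after rescaling
#'   (default 0.05).
#' @param max_tries bound on extinction retries.
#' @return a rooted ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_birth_death_tree <- function(n, birth = 6, death = 2,
                                      median_branch = 0.05,
                                      max_tries = 10000L) {
  stopifnot(n >= 3L, birth > death, death >= 0)
  sim <- NULL
  for (try in seq_len(max_tries)) {
    parent <- NA_integer_   # node table: parent pointer and birth time
    btime <- 0
    dtime <- NA_real_       # death time (NA = alive or internal)
    nnodes <- 1L
    live <- 1L
    t <- 0
    while (length(live) > 0L && length(live) < n) {
      k <- length(live)
      t <- t + stats::rexp(1L, k * (birth + death))
      j <- live[sample.int(k, 1L)]
      if (stats::runif(1L) < birth / (birth + death)) {
        parent <- c(parent, j, j)
        btime <- c(btime, t, t)
        dtime <- c(dtime, NA_real_, NA_real_)
        live <- c(setdiff(live, j), nnodes + 1L, nnodes + 2L)
        nnodes <- nnodes + 2L
      } else {
        live <- setdiff(live, j)
        dtime[j] <- t
      }
    }
    if (length(live) == n) {
      sim <- list(parent = parent, btime = btime, dtime = dtime,
                  nnodes = nnodes, live = live, t = t)
      break
    }
  }
  if (is.null(sim)) stop("birth-death simulation failed to reach ", n,
                         " tips in ", max_tries, " tries")
  parent <- sim$parent; btime <- sim$btime; dtime <- sim$dtime
  nnodes <- sim$nnodes; live <- sim$live; t <- sim$t
  ## nodes without children are tips; live tips end at t, dead at death time
  kids <- which(!is.na(parent))
  haskids <- unique(parent[kids])
  tipn <- setdiff(seq_len(nnodes), haskids)
  end <- ifelse(is.na(dtime), t, dtime)
  firstchild_time <- rep(NA_real_, nnodes)
  for (v in haskids) firstchild_time[v] <- btime[which(parent == v)[1L]]
  elen <- numeric(length(kids))
  for (r in seq_along(kids)) {
    v <- kids[r]
    stop_t <- if (v %in% tipn) end[v] else firstchild_time[v]
    elen[r] <- stop_t - btime[v]
  }
  labs <- paste0("bd", tipn)
  tr <- build_rooted_phylo(parent[kids], kids, elen,
                           stats::setNames(labs, tipn))
  extinct <- labs[!(tipn %in% live)]
  if (length(extinct))
    tr <- ape::drop.tip(tr, extinct, collapse.singles = TRUE)
  tr <- ape::collapse.singles(tr)
  tr$tip.label <- paste0("t", seq_along(tr$tip.label))
  if (!is.null(median_branch)) {
    ul <- ape::unroot(tr)
    tr$edge.length <- tr$edge.length * median_branch / stats::median(ul$edge.length)
  }
  tr
}

## rooted phylo constructor (root may have degree 2); node keys arbitrary
build_rooted_phylo <- function(parent, child, length, tips) {
  keys <- unique(c(parent, child))
  root <- setdiff(parent, child)
  tipkeys <- as.integer(names(tips))
  ntip <- length(tipkeys)
  id <- integer(0)
  id[as.character(tipkeys)] <- seq_len(ntip)
  kids <- split(child, parent)
  ord <- integer(0); stack <- root
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    ord <- c(ord, nd)
    ch <- kids[[as.character(nd)]]
    ch <- ch[!(ch %in% tipkeys)]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  id[as.character(ord)] <- ntip + seq_along(ord)
  tr <- list(edge = cbind(id[as.character(parent)], id[as.character(child)]),
             edge.length = as.numeric(length),
             tip.label = unname(tips), Nnode = length(ord))
  class(tr) <- "phylo"
  tr
}

#' Simulate a JC69 nucleotide alignment along a tree
#'
#' Root states drawn uniformly from {A, C, G, T}; along each branch a site
#' keeps its state with probability `p_same(t)` and otherwise switches to one
#' of the three other states uniformly; sites are independent.
#'
#' @param tree a `phylo` with branch lengths in expected substitutions.
#' @param n_sites number of sites.
#' @return named character vector of tip sequences.
#' @export
simulate_jc69_alignment <- function(tree, n_sites) {
  nuc <- c("A", "C", "G", "T")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  maxnode <- max(tree$edge)
  states <- matrix(0L, nrow = maxnode, ncol = n_sites)
  root <- tree$edge[nrow(tree$edge), 1L]
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  for (i in rev(seq_len(nrow(tree$edge)))) {   # preorder
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    ps <- jc69_transition_prob(TRUE, tree$edge.length[i])
    keep <- stats::runif(n_sites) < ps
    st <- states[p, ]
    sub <- !keep
    if (any(sub)) {
      shift <- sample.int(3L, sum(sub), replace = TRUE)
      st[sub] <- ((st[sub] - 1L + shift) %% 4L) + 1L
    }
    states[v, ] <- st
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(nuc[states[i, ]], collapse = ""), character(1))
  stats::setNames(out, tree$tip.label)
}

#' Build a benchmark data set: tree, alignment, and held-out taxa
#'
#' Simulates a birth-death tree and a JC69 alignment, then holds out taxa
#' (uniformly at random unless given) for online insertion.
#'
#' @param n_taxa total taxon count (the study sizes are 10, 50, 100).
#' @param n_sites alignment length (default 1000).
#' @param birth,death birth-death rates (defaults 6 and 2).
#' @param holdout number of taxa to hold out (study sizes 1, 3, 5), or a
#'   character vector naming them explicitly.
#' @param seed integer seed; the same seed reproduces the benchmark exactly.
#' @param median_branch target median branch length (default 0.05).
#' @param out optional directory; when given, writes `alignment.fasta`,
#'   `true_tree.nwk` and `manifest.json`.
#' @return list with `aln`, `true_tree` (rooted ultrametric), `holdout`
#'   (taxa to insert), `retained` (initial taxa), `manifest`.
#' @export
make_benchmark <- function(n_taxa, n_sites = 1000L, birth = 6, death = 2,
                           holdout = 1L, seed = 1L, median_branch = 0.05,
                           out = NULL) {
  set.seed(seed)
  tree <- simulate_birth_death_tree(n_taxa, birth, death, median_branch)
  aln <- simulate_jc69_alignment(tree, n_sites)
  taxa <- tree$tip.label
  if (is.character(holdout)) {
    stopifnot(all(holdout %in% taxa))
    held <- holdout
  } else {
    stopifnot(holdout >= 1L, holdout < n_taxa)
    held <- sample(taxa, holdout)
  }
  retained <- setdiff(taxa, held)
  manifest <- list(n_taxa = n_taxa, n_sites = n_sites, birth = birth,
                   death = death, holdout = held, seed = seed,
                   median_branch = median_branch,
                   label = paste0("T", n_taxa, "H", length(held), "S", seed))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_fasta(aln, file.path(out, "alignment.fasta"))
    write_fasta(aln[retained], file.path(out, "alignment_reduced.fasta"))
    writeLines(write_newick(tree), file.path(out, "true_tree.nwk"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(aln = aln, true_tree = tree, holdout = held, retained = retained,
       manifest = manifest)
}
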