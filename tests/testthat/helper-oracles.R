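## Independent brute-force oracles and small fixtures shared across tests.
## These deliberately avoid the package's pruning/Fitch code paths.

## JC69 transition matrix by explicit matrix exponential (series evaluation
## of expm(Qt) with the JC69 rate matrix, scaling-and-squaring).
jc_matrix_expm <- function(t) {
  Q <- matrix(1 / 3, 4, 4); diag(Q) <- -1
  A <- Q * t
  k <- max(0, ceiling(log2(max(1, max(abs(A))))))
  A <- A / 2^k
  S <- diag(4); term <- diag(4)
  for (i in 1:20) {
    term <- term %*% A / i
    S <- S + term
  }
  for (i in seq_len(k)) S <- S %*% S
  S
}

## Exhaustive-state log-likelihood: sums over all internal-node state
## assignments per site.  Only feasible for small trees.
brute_loglik <- function(tree, aln) {
  tree <- ape::reorder.phylo(tree, "postorder")
  taxa <- tree$tip.label
  n <- length(taxa)
  seqs <- lapply(aln[taxa], function(s) strsplit(s, "")[[1]])
  S <- length(seqs[[1]])
  nodes <- sort(unique(as.vector(tree$edge)))
  internal <- nodes[nodes > n]
  P <- function(t) {
    e <- exp(-4 * t / 3)
    m <- matrix(0.25 * (1 - e), 4, 4); diag(m) <- 0.25 + 0.75 * e; m
  }
  mats <- lapply(tree$edge.length, P)
  map <- c(A = 1, C = 2, G = 3, T = 4)
  combos <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0
  for (s in seq_len(S)) {
    lik <- 0
    for (r in seq_len(nrow(combos))) {
      st <- integer(max(nodes))
      for (i in seq_len(n)) st[i] <- map[[seqs[[i]][s]]]
      st[internal] <- combos[r, ]
      pr <- 0.25
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * mats[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

## Exhaustive-minimum parsimony score: minimum number of changes over all
## internal state assignments, summed over sites.
brute_parsimony <- function(tree, aln) {
  tree <- ape::reorder.phylo(tree, "postorder")
  taxa <- tree$tip.label
  n <- length(taxa)
  seqs <- lapply(aln[taxa], function(s) strsplit(s, "")[[1]])
  S <- length(seqs[[1]])
  nodes <- sort(unique(as.vector(tree$edge)))
  internal <- nodes[nodes > n]
  map <- c(A = 1, C = 2, G = 3, T = 4)
  combos <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0
  for (s in seq_len(S)) {
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      st <- integer(max(nodes))
      for (i in seq_len(n)) st[i] <- map[[seqs[[i]][s]]]
      st[internal] <- combos[r, ]
      ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
      if (ch < best) best <- ch
    }
    total <- total + best
  }
  total
}

## random binary unrooted tree with exponential branch lengths
random_tree <- function(n, rate = 10,
                        labels = if (n <= 26) LETTERS[seq_len(n)]
                                 else paste0("t", seq_len(n))) {
  topo <- ape::rtopology(n, rooted = FALSE, tip.label = labels)
  topo$edge.length <- stats::rexp(nrow(topo$edge), rate)
  canonical_tree(topo)
}

## random JC69-ish alignment (uniform iid sites; no tree signal)
random_aln <- function(taxa, S) {
  stats::setNames(vapply(taxa, function(i)
    paste(sample(c("A", "C", "G", "T"), S, replace = TRUE), collapse = ""),
    character(1)), taxa)
}

## shared small fixture: 5-taxon tree + alignment with a 6th sequence to add
fix5 <- function() {
  list(tree = parse_newick("((A:0.11,B:0.23):0.07,(C:0.15,D:0.3):0.12,E:0.21);"),
       aln = c(A = "ACGTACGTAA", B = "ACGTACGTCA", C = "ACGAACGTAT",
               D = "TCGAACGTAT", E = "ACGTACTTAA", F = "ACGTACGTAG"))
}

## Brute-force 4-taxon posterior: enumerate the 3 quartet topologies and
## integrate the 5 branch lengths against the Exp(10) prior by importance
## sampling (weights = likelihood), with delta-method standard errors.
## Returns posteriors in the order AB|CD, AC|BD, AD|BC for taxa (A,B,C,D).
quartet_posterior_oracle <- function(aln, M = 1e5, seed = 1, rate = 10) {
  set.seed(seed)
  taxa <- names(aln)[1:4]
  map <- c(A = 1, C = 2, G = 3, T = 4)
  enc <- sapply(aln[taxa], function(s) map[strsplit(s, "")[[1]]])
  pat <- apply(enc, 1, paste, collapse = "")
  cnt <- table(pat)
  upat <- do.call(rbind, strsplit(names(cnt), ""))
  storage.mode(upat) <- "integer"
  ps <- function(t) 0.25 + 0.75 * exp(-4 * t / 3)
  pd <- function(t) 0.25 - 0.25 * exp(-4 * t / 3)
  x <- matrix(stats::rexp(M * 5, rate), M, 5)
  P <- lapply(1:5, function(k) list(s = ps(x[, k]), d = pd(x[, k])))
  topo_logw <- function(pair) {
    grp1 <- pair; grp2 <- setdiff(1:4, pair)
    logw <- numeric(M)
    for (r in seq_len(nrow(upat))) {
      st <- upat[r, ]
      L <- 0
      for (a in 1:4) for (b in 1:4) {
        term <- rep(0.25, M)
        for (i in grp1) term <- term * (if (st[i] == a) P[[i]]$s else P[[i]]$d)
        for (i in grp2) term <- term * (if (st[i] == b) P[[i]]$s else P[[i]]$d)
        term <- term * (if (a == b) P[[5]]$s else P[[5]]$d)
        L <- L + term
      }
      logw <- logw + cnt[r] * log(L)
    }
    logw
  }
  lw <- sapply(list(c(1, 2), c(1, 3), c(1, 4)), topo_logw)
  w <- exp(lw - max(lw))
  Z <- colMeans(w)
  post <- Z / sum(Z)
  se <- sapply(1:3, function(k) {
    den <- rowSums(w)
    g <- (w[, k] - post[k] * den) / mean(den)
    stats::sd(g) / sqrt(M)
  })
  list(post = unname(post), se = se)
}
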