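#' @useDynLib opsmc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize integrate rexp runif rnorm dnorm pnorm dexp
#'   median qnorm rbinom sd setNames cor optim
#' @importFrom utils head tail
NULL

## ---------------------------------------------------------------------------
## Unrooted phylogenetic trees.
##
## Trees are plain ape "phylo" objects kept in a canonical form: unrooted
## (basal trichotomy), edges stored in postorder.  The basal node is an
## arbitrary traversal root; every quantity computed here (likelihood, splits,
## parsimony, total length) is invariant to it.  "Distal" always means the
## child side of an edge, i.e. the side farther from the traversal root.
## ---------------------------------------------------------------------------

#' Put a phylo object into the package's canonical form
#'
#' Unroots the tree (basal trichotomy), validates it (binary, unique tip
#' labels, non-negative branch lengths) and reorders edges into postorder.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return a validated `phylo` in postorder edge order.
#' @export
canonical_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("expected a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  n <- length(tree$tip.label)
  if (n < 3L)
    stop("need at least 3 taxa, got ", n)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  ## binary unrooted tree: N-2 internal nodes, 2N-3 edges
  if (tree$Nnode != n - 2L || nrow(tree$edge) != 2L * n - 3L)
    stop("tree is not a binary unrooted tree (polytomies are not supported): ",
         n, " tips, ", tree$Nnode, " internal nodes, ", nrow(tree$edge), " edges")
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  ape::reorder.phylo(tree, "postorder")
}

#' Parse a Newick string into a tree
#'
#' @param text a single Newick string (terminated by `;`), with branch
#'   lengths after `:`.
#' @return a canonical unrooted `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("malformed Newick string: ", substr(text, 1L, 60L))
  canonical_tree(tree)
}

#' Write a tree as a Newick string
#'
#' Branch lengths are written with 17 significant digits so that
#' parse/write round-trips are lossless.
#'
#' @param tree a `phylo`.
#' @return a Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 17)
}

#' Read a sample of trees from a file
#'
#' Supports NEXUS tree blocks with an optional `translate` table (the MrBayes
#' `.t` dialect) and plain one-Newick-per-line files.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the first non-blank line), `"nexus"` or
#'   `"newick"`.
#' @return a list of canonical `phylo` objects, in file order.
#' @export
read_tree_sample <- function(path, format = c("auto", "nexus", "newick")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- ""
    con <- file(path, "r"); on.exit(close(con))
    while (TRUE) {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L) break
      if (nzchar(trimws(ln))) { first <- trimws(ln); break }
    }
    close(con); on.exit()
    format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- if (format == "nexus") {
    out <- tryCatch(ape::read.nexus(path),
                    error = function(e) stop("failed to read NEXUS trees: ",
                                             conditionMessage(e)))
    if (inherits(out, "phylo")) list(out)
    else lapply(seq_along(out), function(i) out[[i]])  # restores tip labels
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, parse_newick)
  }
  if (length(trees) == 0L) {
    warning("no trees found in ", path)
    return(list())
  }
  lapply(trees, canonical_tree)
}

#' Write a list of trees as a one-Newick-per-line file
#'
#' @param trees list of `phylo`.
#' @param path output path.
#' @export
write_tree_sample <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
}

#' Enumerate the branches of a tree in a stable order
#'
#' Branches are identified by their row index in the postorder edge matrix of
#' the canonical tree; this order is deterministic and stable across calls.
#'
#' @param tree a canonical `phylo`.
#' @return a data.frame with columns `edge` (index), `parent`, `child`,
#'   `length`.
#' @export
enumerate_edges <- function(tree) {
  data.frame(edge = seq_len(nrow(tree$edge)),
             parent = tree$edge[, 1L],
             child  = tree$edge[, 2L],
             length = tree$edge.length)
}

#' Total branch length of a tree
#' @param tree a `phylo`.
#' @return sum of branch lengths.
#' @export
total_length <- function(tree) sum(tree$edge.length)

## Build a canonical phylo from an arbitrary edge table.  Node keys are
## integers (any values); `tips` maps tip node keys to labels, and the order
## of `tips` fixes the tip numbering.
build_phylo <- function(parent, child, length, tips) {
  keys <- unique(c(parent, child))
  root <- setdiff(parent, child)
  if (length(root) != 1L) stop("edge table does not describe a tree")
  tipkeys <- as.integer(names(tips))
  ntip <- length(tipkeys)
  id <- integer(0)
  id[as.character(tipkeys)] <- seq_len(ntip)
  ## preorder numbering of internal nodes
  internal <- c(root, setdiff(keys, c(tipkeys, root)))
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
  edge <- cbind(id[as.character(parent)], id[as.character(child)])
  tr <- list(edge = edge, edge.length = as.numeric(length),
             tip.label = unname(tips), Nnode = length(ord))
  class(tr) <- "phylo"
  canonical_tree(tr)
}

#' Attach a new taxon onto a branch of a tree
#'
#' The chosen branch is split at distance `x` from its child (root-distal)
#' end into a distal part of length `x` and a proximal part of length
#' `|e| - x`; a pendant branch of length `y` leads from the new attachment
#' node to the new leaf.  The length of the attachment branch itself is
#' conserved, so the total tree length grows by exactly `y`.  The input tree
#' is not modified.
#'
#' @param tree a canonical `phylo` with N leaves.
#' @param edge branch index (row of [enumerate_edges()]).
#' @param x distal length, in `[0, |e|]`.
#' @param y pendant branch length, `>= 0`.
#' @param name label of the new leaf (must not already be present).
#' @return a canonical `phylo` with N+1 leaves.
#' @export
attach_taxon <- function(tree, edge, x, y, name) {
  ne <- nrow(tree$edge)
  stopifnot(edge >= 1L, edge <= ne)
  len <- tree$edge.length[edge]
  if (x < 0 || x > len + 1e-12)
    stop("distal length x = ", x, " outside [0, ", len, "]")
  x <- min(max(x, 0), len)
  if (y < 0) stop("pendant length must be >= 0")
  if (name %in% tree$tip.label)
    stop("taxon '", name, "' is already a leaf")
  maxnode <- max(tree$edge)
  z <- maxnode + 1L         # new internal node
  w <- maxnode + 2L         # new tip (temporary key)
  p <- tree$edge[edge, 1L]; cdl <- tree$edge[edge, 2L]
  parent <- c(tree$edge[-edge, 1L], p, z, z)
  child  <- c(tree$edge[-edge, 2L], z, cdl, w)
  elen   <- c(tree$edge.length[-edge], len - x, x, y)
  ntip <- length(tree$tip.label)
  tips <- setNames(c(tree$tip.label, name), c(seq_len(ntip), w))
  build_phylo(parent, child, elen, tips)
}

#' Remove a leaf from a tree, merging the two branches at its attachment node
#'
#' Inverse of [attach_taxon()].  The two branches incident to the (degree-3)
#' attachment node are merged into one branch with the summed length.
#'
#' @param tree a canonical `phylo` with at least 4 leaves.
#' @param name leaf label to remove.
#' @return a list with `tree` (the reduced canonical `phylo`),
#'   `merged_edge` (index of the merged branch in the reduced tree),
#'   `merged_length`, and `pendant_length`.
#' @export
detach_taxon <- function(tree, name) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop("cannot remove a leaf from a tree with fewer than 4 leaves")
  tip <- match(name, tree$tip.label)
  if (is.na(tip)) stop("no leaf named '", name, "'")
  pe <- which(tree$edge[, 2L] == tip)
  z <- tree$edge[pe, 1L]
  ylen <- tree$edge.length[pe]
  root <- ntip + 1L
  inc <- setdiff(which(tree$edge[, 1L] == z | tree$edge[, 2L] == z), pe)
  edge <- tree$edge; elen <- tree$edge.length
  if (z != root) {
    ## z has parent p and one remaining child c: merge (p,z)+(z,c)
    up <- inc[edge[inc, 2L] == z]
    dn <- inc[edge[inc, 1L] == z]
    p <- edge[up, 1L]; cc <- edge[dn, 2L]
    keep <- setdiff(seq_len(nrow(edge)), c(pe, up, dn))
    parent <- c(edge[keep, 1L], p)
    child  <- c(edge[keep, 2L], cc)
    len    <- c(elen[keep], elen[up] + elen[dn])
    below <- cc
  } else {
    ## z is the basal trichotomy: two children remain; root at an internal one
    dn <- inc
    c1 <- edge[dn[1L], 2L]; c2 <- edge[dn[2L], 2L]
    ## merged edge connects c1 and c2; root at whichever is internal
    if (c1 > ntip) { newroot <- c1; other <- c2 } else { newroot <- c2; other <- c1 }
    if (newroot <= ntip) stop("cannot detach: resulting tree degenerate")
    keep <- setdiff(seq_len(nrow(edge)), c(pe, dn))
    parent <- c(edge[keep, 1L], newroot)
    child  <- c(edge[keep, 2L], other)
    len    <- c(elen[keep], elen[dn[1L]] + elen[dn[2L]])
    ## reorient edges: the component that was above newroot must now hang below
    tb <- reorient_edges(parent, child, len, newroot)
    parent <- tb$parent; child <- tb$child; len <- tb$length
    below <- other
  }
  oldtips <- setdiff(seq_len(ntip), tip)
  tips <- setNames(tree$tip.label[oldtips], oldtips)
  out <- build_phylo(parent, child, len, tips)
  ## locate the merged edge in the reduced tree: child side carries the same
  ## tip set as `below` did (or its complement, if the rooting flipped)
  target <- tipset_below(tree, below, exclude = tip)
  me <- match_edge_by_tipset(out, target)
  list(tree = out, merged_edge = me,
       merged_length = out$edge.length[me], pendant_length = ylen)
}

## Re-root an edge list (given as parent/child vectors) at `root` by flipping
## edge directions along the path where needed.
reorient_edges <- function(parent, child, length, root) {
  m <- length(parent)
  adj <- list()
  for (i in seq_len(m)) {
    adj[[as.character(parent[i])]] <- c(adj[[as.character(parent[i])]], i)
    adj[[as.character(child[i])]]  <- c(adj[[as.character(child[i])]], i)
  }
  np <- integer(m); nc <- integer(m)
  seen <- integer(0); stack <- root
  used <- logical(m)
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (i in adj[[as.character(nd)]]) {
      if (used[i]) next
      used[i] <- TRUE
      np[i] <- nd
      nc[i] <- if (parent[i] == nd) child[i] else parent[i]
      stack <- c(stack, nc[i])
    }
  }
  list(parent = np, child = nc, length = length)
}

## Tip labels in the subtree below node `node` (by the tree's stored rooting),
## optionally excluding one tip index.
tipset_below <- function(tree, node, exclude = NA_integer_) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    labs <- tree$tip.label[node]
  } else {
    desc <- node
    repeat {
      kids <- tree$edge[tree$edge[, 1L] %in% desc, 2L]
      newd <- union(desc, kids)
      if (length(newd) == length(desc)) break
      desc <- newd
    }
    tipidx <- desc[desc <= ntip]
    if (!is.na(exclude)) tipidx <- setdiff(tipidx, exclude)
    labs <- tree$tip.label[tipidx]
  }
  sort(labs)
}

## Find the edge of `tree` whose induced bipartition has `labs` (sorted tip
## labels) on one side.
match_edge_by_tipset <- function(tree, labs) {
  ss <- splits(tree, include_trivial = TRUE)
  full <- sort(tree$tip.label)
  key1 <- paste(labs, collapse = "\r")
  key2 <- paste(setdiff(full, labs), collapse = "\r")
  for (i in seq_along(ss$edge)) {
    k <- paste(ss$side[[i]], collapse = "\r")
    kc <- paste(setdiff(full, ss$side[[i]]), collapse = "\r")
    if (k == key1 || k == key2 || kc == key1) return(ss$edge[i])
  }
  stop("internal error: merged edge not found")
}

#' Bipartitions (splits) induced by the branches of a tree
#'
#' Each branch induces a bipartition of the taxon set.  Splits are stored in
#' a canonical orientation: the reported side is the side *not* containing
#' the alphabetically smallest taxon, so the representation is independent of
#' the traversal root.
#'
#' @param tree a canonical `phylo`.
#' @param include_trivial include pendant-branch (single-leaf) splits?
#' @return a list with `key` (character id per split), `side` (list of sorted
#'   taxon vectors), `edge` (inducing branch index), `length` (branch length),
#'   `trivial` (logical).
#' @export
splits <- function(tree, include_trivial = FALSE) {
  ntip <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) below[[i]] <- i
  ## postorder: children come before parents
  for (i in seq_len(ne)) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  anchor <- which.min(rank(tree$tip.label))  # alphabetically smallest tip
  key <- character(ne); side <- vector("list", ne)
  trivial <- logical(ne)
  for (i in seq_len(ne)) {
    s <- below[[tree$edge[i, 2L]]]
    if (anchor %in% s) s <- setdiff(seq_len(ntip), s)
    labs <- sort(tree$tip.label[s])
    side[[i]] <- labs
    key[i] <- paste(labs, collapse = "|")
    trivial[i] <- length(s) <= 1L || length(s) >= ntip - 1L
  }
  keep <- if (include_trivial) seq_len(ne) else which(!trivial)
  list(key = key[keep], side = side[keep], edge = keep,
       length = tree$edge.length[keep], trivial = trivial[keep])
}
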