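test_that("JC69 transition probabilities match the matrix exponential", {
  expect_equal(jc69_transition_prob(TRUE, 0), 1)
  expect_equal(jc69_transition_prob(FALSE, 0), 0)
  expect_equal(jc69_transition_prob(TRUE, 1e6), 0.25, tolerance = 1e-12)
  expect_equal(jc69_transition_prob(FALSE, 1e6), 0.25, tolerance = 1e-12)
  for (t in c(0.01, 0.1, 0.7, 2.3)) {
    Pm <- jc_matrix_expm(t)
    expect_equal(jc69_transition_prob(TRUE, t), Pm[1, 1], tolerance = 1e-10)
    expect_equal(jc69_transition_prob(FALSE, t), Pm[1, 2], tolerance = 1e-10)
  }
  expect_equal(jc69_transition_prob(TRUE, 0.1), 0.906380, tolerance = 1e-6)
  expect_equal(jc69_transition_prob(TRUE, 0.3) + 3 * jc69_transition_prob(FALSE, 0.3), 1)
  expect_error(jc69_transition_prob(TRUE, -0.1), ">= 0")
})

test_that("pruning equals the exhaustive internal-state sum", {
  set.seed(21)
  for (i in 1:3) {
    tr <- random_tree(5)
    aln <- random_aln(LETTERS[1:5], 8)
    expect_equal(log_likelihood(tr, aln), brute_loglik(tr, aln),
                 tolerance = 1e-10)
  }
  ## two-sequence closed form: zero-length branches pin the inner node, so
  ## identical states at total distance 0.1 give log(0.25 * p_same(0.1))
  tr <- parse_newick("(A:0.1,B:0.0,C:0.0);")
  ll <- log_likelihood(tr, c(A = "G", B = "G", C = "G"))
  expect_equal(ll, log(0.25 * jc69_transition_prob(TRUE, 0.1)),
               tolerance = 1e-10)
  expect_equal(ll, -1.48455, tolerance = 1e-4)
})

test_that("saturated branches drive the likelihood to the stationary limit", {
  ## at saturation every tip is an independent uniform draw per site, so the
  ## joint probability of a site is (1/4)^N
  tr <- parse_newick("((A:1000,B:1000):1000,C:1000,D:1000);")
  aln <- random_aln(LETTERS[1:4], 10)
  expect_equal(log_likelihood(tr, aln), 10 * 4 * log(0.25), tolerance = 1e-3)
})

test_that("log-likelihood is invariant to the traversal root", {
  set.seed(23)
  for (i in 1:4) {
    tr <- random_tree(8)
    aln <- random_aln(LETTERS[1:8], 30)
    base <- log_likelihood(tr, aln)
    rr <- canonical_tree(ape::root(tr, outgroup = tr$tip.label[i + 1],
                                   resolve.root = FALSE))
    expect_equal(log_likelihood(rr, aln), base, tolerance = 1e-9)
  }
})

test_that("gaps and ambiguity codes act as partial/missing observations", {
  tr <- parse_newick("(A:0.1,B:0.2,C:0.15);")
  ## all-missing taxon contributes nothing
  ll1 <- log_likelihood(tr, c(A = "ACGT", B = "AGGT", C = "????"))
  tr2 <- parse_newick("(A:0.1,B:0.2,X:1000);")
  ll2 <- log_likelihood(tr2, c(A = "ACGT", B = "AGGT", X = "ACGT"))
  expect_equal(ll1, ll2 - 4 * log(0.25), tolerance = 1e-6)
  expect_error(log_likelihood(tr, c(A = "ACGT", B = "AGGT")), "C")
})

test_that("attachment_loglik equals a full recompute", {
  set.seed(31)
  tr <- random_tree(10)
  aln <- random_aln(c(LETTERS[1:10], "Z"), 40)
  ed <- enumerate_edges(tr)
  for (i in 1:20) {
    e <- sample.int(nrow(ed), 1)
    x <- runif(1, 0, ed$length[e])
    y <- rexp(1, 10)
    fast <- attachment_loglik(tr, aln, "Z", e, x, y)
    full <- log_likelihood(attach_taxon(tr, e, x, y, "Z"), aln)
    expect_equal(fast, full, tolerance = 1e-10)
  }
  ## boundary placements are exact too
  e <- which.max(ed$length)
  for (x in c(0, ed$length[e])) {
    expect_equal(attachment_loglik(tr, aln, "Z", e, x, 0.05),
                 log_likelihood(attach_taxon(tr, e, x, 0.05, "Z"), aln),
                 tolerance = 1e-10)
  }
})

test_that("a distant pendant taxon decouples from the tree", {
  f <- fix5()
  base <- log_likelihood(f$tree, f$aln[1:5])
  far <- attachment_loglik(f$tree, f$aln, "F", 1L, 0.03, 1000)
  expect_equal(far, base + 10 * log(0.25), tolerance = 1e-3)
})

test_that("analytic branch derivatives match finite differences", {
  f <- fix5()
  ctx <- opsmc:::attach_ctx(f$tree, f$aln, "F")
  h <- 1e-5
  for (e in c(2L, 4L)) {
    le <- f$tree$edge.length[e]
    x0 <- le / 3; y0 <- 0.07
    g <- function(x, y) opsmc:::ctx_attach(ctx, e, x, y)[1]
    d <- opsmc:::ctx_attach(ctx, e, x0, y0, derivs = TRUE)
    expect_equal(d[2], (g(x0 + h, y0) - g(x0 - h, y0)) / (2 * h), tolerance = 1e-5)
    expect_equal(d[3], (g(x0 + h, y0) - 2 * g(x0, y0) + g(x0 - h, y0)) / h^2,
                 tolerance = 1e-3)
    expect_equal(d[4], (g(x0, y0 + h) - g(x0, y0 - h)) / (2 * h), tolerance = 1e-5)
    expect_equal(d[5], (g(x0, y0 + h) - 2 * g(x0, y0) + g(x0, y0 - h)) / h^2,
                 tolerance = 1e-3)
  }
})

test_that("optimize_attachment agrees with a grid search and duplicates pin y to 0", {
  ## an alignment with real signal: simulate on a 7-taxon tree, then drop
  ## one taxon and ask where it attaches on the reduced tree
  set.seed(41)
  tr7 <- random_tree(7, labels = c(LETTERS[1:6], "Z"))
  aln <- simulate_jc69_alignment(tr7, 200)
  tr <- detach_taxon(tr7, "Z")$tree
  ed <- enumerate_edges(tr)
  e <- which.max(ed$length)
  opt <- optimize_attachment(tr, aln, "Z", e)
  ## 200 x 200 grid over [0,|e|] x [0,1]
  xs <- seq(0, ed$length[e], length.out = 200)
  ys <- seq(0, 1, length.out = 200)
  ctx <- opsmc:::attach_ctx(tr, aln, "Z")
  vals <- outer(seq_along(xs), seq_along(ys), Vectorize(function(i, j)
    opsmc:::ctx_attach(ctx, e, xs[i], ys[j])[1]))
  best <- arrayInd(which.max(vals), dim(vals))
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  expect_lt(abs(opt$x_mle - xs[best[1]]), dx + 1e-12)
  expect_lt(abs(opt$y_mle - ys[best[2]]), dy + 1e-12)
  ## observed information against central finite differences
  h <- 1e-4
  g <- function(x) opsmc:::ctx_attach(ctx, e, x, opt$y_mle)[1]
  if (opt$x_mle > h && opt$x_mle < ed$length[e] - h) {
    fd <- -(g(opt$x_mle + h) - 2 * g(opt$x_mle) + g(opt$x_mle - h)) / h^2
    expect_equal(opt$info_x, fd, tolerance = 1e-3)
  }
  ## attaching a duplicate of leaf A on A's pendant edge
  f <- fix5()
  aln2 <- c(f$aln[1:5], Z = unname(f$aln["A"]))
  ea <- which(enumerate_edges(f$tree)$child == which(f$tree$tip.label == "A"))
  opt2 <- optimize_attachment(f$tree, aln2, "Z", ea)
  expect_lte(opt2$y_mle, 1e-4)
})
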