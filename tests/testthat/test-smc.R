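test_that("unnormalized log posterior adds the branch prior", {
  tr <- parse_newick("(A:0.1,B:0.1,C:0.1);")
  aln <- c(A = "ACGT", B = "ACGT", C = "AGGT")
  expect_equal(unnormalized_log_posterior(tr, aln),
               log_likelihood(tr, aln) + 3 * (log(10) - 1),
               tolerance = 1e-12)
  ## zero-length branches contribute log(rate) each
  tr0 <- parse_newick("(A:0,B:0,C:0);")
  expect_equal(unnormalized_log_posterior(tr0, aln),
               log_likelihood(tr0, aln) + 3 * log(10), tolerance = 1e-12)
  ## cache consistency after attachment surgery
  t2 <- attach_taxon(tr, 1L, 0.05, 0.2, "D")
  expect_equal(unnormalized_log_posterior(t2, c(aln, D = "ACTT")),
               log_likelihood(t2, c(aln, D = "ACTT")) +
                 sum(dexp(t2$edge.length, 10, log = TRUE)))
})

test_that("the ESS formula behaves at its extremes", {
  expect_equal(ess(rep(1 / 3, 3)), 3)
  expect_equal(ess(c(1, 0, 0)), 1)
  expect_equal(ess(c(0.5, 0.25, 0.25)), 8 / 3, tolerance = 1e-12)
  expect_equal(ess(rep(0.2, 10)), 10)  # unnormalized input is fine
  expect_error(ess(c(0, 0)), "collapse")
  expect_error(ess(c(-1, 2)), "negative")
})

test_that("stratified resampling has the right first two moments", {
  set.seed(71)
  ## equal weights, K_out = K: a permutation-free identity draw
  idx <- stratified_resample(rep(1 / 6, 6))
  expect_equal(sort(idx), 1:6)
  expect_equal(stratified_resample(c(1, 0, 0, 0), 5), rep(1L, 5))
  ## copy counts: mean K * w_i, variance below multinomial
  w <- c(0.4, 0.3, 0.2, 0.1)
  K <- 8
  counts <- t(replicate(4000, tabulate(stratified_resample(w, K), 4)))
  for (i in 1:4) {
    se <- sd(counts[, i]) / sqrt(nrow(counts))
    expect_lt(abs(mean(counts[, i]) - K * w[i]), 3 * se)
    expect_lt(var(counts[, i]), K * w[i] * (1 - w[i]))
  }
})

test_that("particle initialization replicates trees with equal weights", {
  set.seed(73)
  trees <- replicate(5, random_tree(5), simplify = FALSE)
  aln <- random_aln(LETTERS[1:5], 10)
  ps <- init_particles(trees, 3L, aln)
  expect_length(ps$trees, 15L)
  expect_equal(ps$weights, rep(1 / 15, 15))
  expect_equal(ps$tree_id, rep(1:5, each = 3))
  expect_equal(ps$log_post[1],
               unnormalized_log_posterior(trees[[1]], aln))
  ## factor 1 keeps the input trees untouched
  ps1 <- init_particles(trees, 1L, aln)
  expect_identical(ps1$trees, trees)
  ## heterogeneous taxon sets are rejected
  bad <- c(trees[1:4], list(random_tree(5, labels = letters[1:5])))
  expect_error(init_particles(bad, 1L, aln), "same taxon set")
})

test_that("an exactly-cancelling proposal leaves unit weights and full ESS", {
  ## With a data-free alignment the likelihood is constant, and for ~UUP on
  ## a tree with all branch lengths equal the posterior-ratio-over-Q weight
  ## is identical across particles: ESS must stay exactly K.
  tr <- parse_newick("(A:0.1,(B:0.1,C:0.1):0.1,D:0.1);")
  trees <- rep(list(tr), 10)
  aln <- setNames(rep(strrep("?", 5), 5), c(LETTERS[1:4], "E"))
  set.seed(77)
  sys <- init_particles(trees, 2L, aln)
  sys2 <- smc_step(sys, aln, "E", "~UUP")
  expect_equal(sys2$weights, rep(1 / 20, 20), tolerance = 1e-12)
  expect_equal(tail(sys2$ess_trace, 1), 20)
})

test_that("one SMC generation grows every particle by one taxon", {
  set.seed(79)
  trees <- replicate(6, random_tree(5), simplify = FALSE)
  aln <- random_aln(c(LETTERS[1:5], "Z"), 30)
  sys <- init_particles(trees, 2L, aln[LETTERS[1:5]])
  sys2 <- smc_step(sys, aln, "Z", "PAF")
  expect_equal(sys2$generation, 1L)
  for (t in sys2$trees) {
    expect_length(t$tip.label, 6L)
    expect_equal(nrow(t$edge), 9L)
  }
  expect_equal(sum(sys2$weights), 1)
  ## cached log posterior matches recomputation
  i <- which.max(sys2$weights)
  expect_equal(sys2$log_post[i],
               unnormalized_log_posterior(sys2$trees[[i]], aln),
               tolerance = 1e-8)
})

test_that("weight updates match independent recomputation", {
  set.seed(83)
  trees <- replicate(4, random_tree(4), simplify = FALSE)
  aln <- random_aln(c(LETTERS[1:4], "Z"), 25)
  sys <- init_particles(trees, 1L, aln[LETTERS[1:4]],
                        opsmc_config(resample_threshold = 0))
  cfg <- opsmc_config(resample_threshold = 0)
  set.seed(91)
  sys2 <- smc_step(sys, aln, "Z", "~UUP", cfg)
  ## replay the same draws and recompute each weight from scratch
  set.seed(91)
  lw <- numeric(4)
  for (i in 1:4) {
    d <- opsmc:::propose_ctx(opsmc:::attach_ctx(trees[[i]], aln, "Z"),
                             parse_kernel("~UUP"), cfg)
    t2 <- attach_taxon(trees[[i]], d$edge, d$x, d$y, "Z")
    lw[i] <- log(sys$weights[i]) +
      unnormalized_log_posterior(t2, aln) -
      unnormalized_log_posterior(trees[[i]], aln[LETTERS[1:4]]) -
      (-log(nrow(trees[[i]]$edge)) - log(trees[[i]]$edge.length[d$edge]) +
         dexp(d$y, 10, log = TRUE))
  }
  expect_equal(sys2$weights, exp(lw) / sum(exp(lw)), tolerance = 1e-8)
})

test_that("run_online is deterministic given a seed and handles zero taxa", {
  set.seed(87)
  trees <- replicate(5, random_tree(5), simplify = FALSE)
  aln <- random_aln(c(LETTERS[1:5], "Y", "Z"), 40)
  s0 <- run_online(trees, aln[LETTERS[1:5]], character(0), "LAF", 2L, seed = 3)
  expect_equal(s0$generation, 0L)
  expect_equal(s0$weights, rep(1 / 10, 10))
  a <- run_online(trees, aln, c("Y", "Z"), "LAF", 2L, seed = 5)
  b <- run_online(trees, aln, c("Y", "Z"), "LAF", 2L, seed = 5)
  expect_identical(a$weights, b$weights)
  expect_identical(lapply(a$trees, write_newick), lapply(b$trees, write_newick))
  expect_length(a$trees[[1]]$tip.label, 7L)
  expect_length(a$ess_trace, 2L)
})

test_that("posterior expectations average with the particle weights", {
  set.seed(93)
  trees <- replicate(4, random_tree(5), simplify = FALSE)
  aln <- random_aln(LETTERS[1:5], 10)
  sys <- init_particles(trees, 1L, aln)
  expect_equal(posterior_expectation(sys, function(t) 1), 1)
  expect_equal(posterior_expectation(sys, total_length),
               mean(vapply(trees, total_length, numeric(1))))
  sys$weights <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(posterior_expectation(sys, total_length),
               sum(sys$weights * vapply(trees, total_length, numeric(1))))
})

test_that("resampling leaves weighted expectations unchanged on average", {
  set.seed(95)
  w <- runif(12); w <- w / sum(w)
  phi <- rnorm(12)
  target <- sum(w * phi)
  est <- replicate(4000, mean(phi[stratified_resample(w)]))
  expect_lt(abs(mean(est) - target), 3 * sd(est) / sqrt(length(est)))
})
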