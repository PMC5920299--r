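test_that("kernel codes parse and validate", {
  k <- parse_kernel("LAF")
  expect_equal(k[c("step1", "step2", "step3")],
               list(step1 = "L", step2 = "A", step3 = "F"))
  expect_true(k$heated)
  expect_equal(k$alpha, 0.05)
  k2 <- parse_kernel("~LNM")
  expect_false(k2$heated)
  expect_equal(k2$alpha, 1)
  expect_false(parse_kernel("~UUP")$heated)
  expect_error(parse_kernel("XAF"), "Step 1")
  expect_error(parse_kernel("LXF"), "Step 2")
  expect_error(parse_kernel("LAX"), "Step 3")
  expect_error(parse_kernel("LAFF"), "three letters")
})

test_that("heating flattens step-1 probabilities as alpha shrinks", {
  probs <- c(0.9, 0.1)
  expect_equal(opsmc:::heat_probs(probs, 1), probs)
  expect_equal(opsmc:::heat_probs(probs, 0.05), c(0.52744, 0.47256),
               tolerance = 1e-5)
  ## parsimony example S = (2, 4)
  g <- parsimony_weights(c(2, 4))
  expect_equal(g, c(0.880797, 0.119203), tolerance = 1e-6)
  expect_equal(opsmc:::heat_probs(g, 0.05), c(0.524979, 0.475021),
               tolerance = 1e-6)
  ## alpha -> 0 approaches uniform on any distribution
  set.seed(2)
  p <- parsimony_weights(sample(0:9, 7, TRUE))
  expect_equal(opsmc:::heat_probs(p, 1e-6), rep(1 / 7, 7), tolerance = 1e-4)
})

test_that("step 1 uniform is uniform over 2n-3 branches", {
  set.seed(4)
  tr10 <- random_tree(10)
  s <- step1_uniform(tr10)
  expect_equal(s$probs, rep(1 / 17, 17))
  expect_equal(s$log_q, -log(17))
  expect_equal(step1_uniform(parse_newick("(A:1,B:1,C:1);"))$log_q, -log(3))
  draws <- replicate(20000, step1_uniform(tr10)$edge)
  cs <- chisq.test(table(factor(draws, levels = 1:17)))
  expect_gt(cs$p.value, 0.01)
})

test_that("guided step 1 targets the right branch for a duplicate sequence", {
  set.seed(8)
  tr <- random_tree(6)
  aln <- random_aln(LETTERS[1:6], 80)
  aln <- c(aln, Z = unname(aln["D"]))
  pend_d <- which(tr$edge[, 2] == which(tr$tip.label == "D"))
  sl <- step1_likelihood(tr, aln, "Z", alpha = 1)
  expect_equal(which.max(sl$probs), pend_d)
  expect_gt(sl$probs[pend_d], 0.99)   # unheated ranks the true edge first
  sp <- step1_parsimony(tr, aln, "Z", alpha = 1)
  expect_equal(which.max(sp$probs), pend_d)
  ## heated version still ranks it first but is much flatter
  sh <- step1_likelihood(tr, aln, "Z", alpha = 0.05)
  expect_equal(which.max(sh$probs), pend_d)
  expect_lt(max(sh$probs), max(sl$probs))
  expect_equal(sum(sh$probs), 1)
})

test_that("step 2 proposals are normalized densities on [0, |e|]", {
  set.seed(12)
  s <- step2_uniform(0.4)
  expect_equal(s$log_q, log(2.5))
  expect_true(s$x >= 0 && s$x <= 0.4)
  xs <- replicate(20000, step2_uniform(0.4)$x)
  expect_lt(abs(mean(xs) - 0.2), 3 * sd(xs) / sqrt(length(xs)))
  ## degenerate edge: point mass at 0 with zero log-density
  expect_equal(step2_uniform(1e-12), list(x = 0, log_q = 0))
  expect_equal(step2_normal(1e-12, 0)$x, 0)
  ## truncated normal integrates to 1 (N and A variants)
  for (mu in c(0, 0.17, 0.4)) {
    q <- integrate(function(x)
      exp(vapply(x, function(z) opsmc:::dtruncnorm01(z, mu, 0.1, 0.4),
                 numeric(1))), 0, 0.4, rel.tol = 1e-10)$value
    expect_equal(q, 1, tolerance = 1e-8)
  }
  ## A-variant scale is the inverse root of the observed information
  set.seed(13)
  draws <- replicate(4000, step2_asymptotic(1, 0.5, 400)$x)
  expect_equal(sd(draws), 0.05, tolerance = 0.05)
  ## x_mle at the boundary: all draws stay in [0, |e|], histogram mode at 0
  d0 <- replicate(4000, step2_normal(1, 0)$x)
  expect_true(all(d0 >= 0 & d0 <= 1))
  expect_gt(sum(d0 < 0.1), sum(d0 >= 0.1 & d0 < 0.2))
})

test_that("step 2 A matches the curvature of an exact Gaussian curve", {
  ## quadratic log-likelihood with curvature -1/sigma^2: the asymptotic
  ## proposal reproduces that Gaussian (up to truncation)
  sigma <- 0.07
  info <- 1 / sigma^2
  set.seed(14)
  xs <- replicate(20000, step2_asymptotic(1, 0.5, info)$x)
  expect_equal(mean(xs), 0.5, tolerance = 0.005)
  expect_equal(sd(xs), sigma, tolerance = 0.02)
})

test_that("step 3 densities follow their closed forms", {
  set.seed(21)
  s <- step3_prior(10)
  expect_equal(s$log_q, log(10) - 10 * s$y)
  expect_equal(dexp(0, 10), 10)
  expect_equal(dexp(0.1, 10), 10 * exp(-1), tolerance = 1e-12)
  ys <- replicate(30000, step3_prior(10)$y)
  expect_lt(abs(mean(ys) - 0.1), 3 * sd(ys) / sqrt(length(ys)))
  ## M: exponential with mean y_mle
  expect_equal(dexp(0.2, 1 / 0.2), 5 * exp(-1), tolerance = 1e-12)
  ym <- replicate(30000, step3_ml(0.2)$y)
  expect_lt(abs(mean(ym) - 0.2), 3 * sd(ym) / sqrt(length(ym)))
  ## y_mle = 0 floors the mean at 1e-6
  y0 <- replicate(100, step3_ml(0)$y)
  expect_lt(max(y0), 1e-4)
})

test_that("step 3 lcfit concentrates near zero for duplicate sequences", {
  set.seed(31)
  tr <- random_tree(6)
  aln <- random_aln(LETTERS[1:6], 200)
  aln <- c(aln, Z = unname(aln["B"]))
  pend_b <- which(tr$edge[, 2] == which(tr$tip.label == "B"))
  ys <- replicate(200, step3_lcfit(tr, aln, "Z", pend_b,
                                   tr$edge.length[pend_b] / 2)$y)
  expect_lt(median(ys), 0.01)
})

test_that("step 3 lcfit density agrees with independent quadrature", {
  set.seed(33)
  tr <- random_tree(6)
  aln <- random_aln(c(LETTERS[1:6], "Z"), 300)
  e <- which.max(tr$edge.length)
  s3 <- step3_lcfit(tr, aln, "Z", e, tr$edge.length[e] / 2, prior_rate = 10)
  expect_true(is.finite(s3$log_q))
  expect_gte(s3$y, 0)
  if (isFALSE(s3$fallback)) {
    ld <- opsmc:::lcfit_log_density(s3$fit, 10, s3$y)
    expect_equal(s3$log_q, ld, tolerance = 1e-6)
    tmax <- opsmc:::lcfit_tmax(s3$fit, 10)
    q <- integrate(function(t) exp(vapply(t, function(z)
      opsmc:::lcfit_log_density(s3$fit, 10, z), numeric(1))),
      0, tmax, rel.tol = 1e-8)$value
    expect_equal(q, 1, tolerance = 1e-5)
  }
})

test_that("composite proposals add their step densities", {
  f <- fix5()
  set.seed(41)
  for (code in c("~UUP", "~LNM", "LAF", "PAF", "~PUM", "LUP")) {
    d <- propose(code, f$tree, f$aln, "F")
    expect_equal(d$log_q, d$log_q1 + d$log_q2 + d$log_q3)
    expect_true(is.finite(d$log_q))
    expect_true(d$x >= 0 && d$x <= f$tree$edge.length[d$edge])
    expect_gte(d$y, 0)
    ## reported log-likelihood equals the full recompute on the new tree
    t2 <- attach_taxon(f$tree, d$edge, d$x, d$y, "F")
    expect_equal(d$loglik, log_likelihood(t2, f$aln), tolerance = 1e-8)
  }
  ## ~UUP on a 3-leaf tree with all |e| = 0.3 has a closed-form density
  tr3 <- parse_newick("(A:0.3,B:0.3,C:0.3);")
  aln3 <- c(A = "ACGTA", B = "ACGTT", C = "ACTTA", D = "AGGTA")
  d <- propose("~UUP", tr3, aln3, "D")
  expect_equal(d$log_q, -log(3) - log(0.3) + log(10) - 10 * d$y,
               tolerance = 1e-12)
})

test_that("the total ~UUP proposal density integrates to one by Monte Carlo", {
  ## E_q[ 1{y <= c} / q ] equals the Lebesgue measure of the truncated
  ## support, sum_e |e| * c -- so q is a proper joint density over (e, x, y)
  tr <- parse_newick("(A:0.2,(B:0.1,C:0.25):0.15,D:0.3);")
  aln <- c(A = "ACGTA", B = "ACGTT", C = "ACTTA", D = "AGGTA", E = "ACGTA")
  set.seed(51)
  n <- 20000
  cc <- 0.2
  vals <- replicate(n, {
    d <- propose("~UUP", tr, aln, "E")
    exp(-d$log_q) * (d$y <= cc)
  })
  expect_lt(abs(mean(vals) - sum(tr$edge.length) * cc),
            3 * sd(vals) / sqrt(n))
})

test_that("caching step-1 distributions does not change the draws", {
  f <- fix5()
  cfg <- opsmc_config()
  ctx <- opsmc:::attach_ctx(f$tree, f$aln, "F")
  kern <- parse_kernel("PAF")
  cache <- new.env()
  set.seed(61); d1 <- opsmc:::propose_ctx(ctx, kern, cfg, cache)
  set.seed(61); d2 <- opsmc:::propose_ctx(ctx, kern, cfg, cache)  # warm cache
  set.seed(61); d3 <- opsmc:::propose_ctx(ctx, kern, cfg, NULL)   # no cache
  expect_identical(d1, d2)
  expect_identical(d1, d3)
})
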