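## ---------------------------------------------------------------------------
## The three-step attachment proposal family.  A kernel is a three-letter
## code: Step 1 (attachment branch) in {U, L, P}, Step 2 (distal position) in
## {U, N, A}, Step 3 (pendant length) in {P, M, F}.  A leading "~" marks the
## unheated Step 1 variant; without it, likelihood/parsimony Step 1
## probabilities are flattened by raising them to the power alpha (0.05 by
## default) and renormalizing.  Examples: "~UUP" (fully unguided), "LAF"
## (heated likelihood + asymptotic normal + lcfit).
## ---------------------------------------------------------------------------

#' Parse a three-letter proposal kernel code
#'
#' @param code e.g. `"LAF"`, `"~UUP"`, `"~LNM"`, `"PAF"`.
#' @param alpha heating exponent in `(0, 1]` for heated Step 1 variants.
#' @return list with `step1`, `step2`, `step3`, `heated`, `alpha`, `code`.
#' @export
parse_kernel <- function(code, alpha = 0.05) {
  stopifnot(is.character(code), length(code) == 1L)
  heated <- !startsWith(code, "~")
  letters3 <- sub("^~", "", code)
  if (nchar(letters3) != 3L)
    stop("kernel code must be three letters with an optional leading '~': ", code)
  s1 <- substr(letters3, 1L, 1L)
  s2 <- substr(letters3, 2L, 2L)
  s3 <- substr(letters3, 3L, 3L)
  if (!s1 %in% c("U", "L", "P")) stop("Step 1 letter must be U, L or P: ", code)
  if (!s2 %in% c("U", "N", "A")) stop("Step 2 letter must be U, N or A: ", code)
  if (!s3 %in% c("P", "M", "F")) stop("Step 3 letter must be P, M or F: ", code)
  if (s1 == "U") heated <- FALSE  # uniform is its own heated version
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  list(step1 = s1, step2 = s2, step3 = s3, heated = heated,
       alpha = if (heated) alpha else 1, code = code)
}

#' Run configuration for proposals and the SMC engine
#'
#' @param prior_rate rate of the exponential branch-length prior
#'   (default 10, i.e. mean 0.1).
#' @param pendant_rate rate of the exponential pendant proposal / prior used
#'   by Step 3 P and F (default 10).
#' @param alpha heating exponent for heated Step 1 variants.
#' @param resample_threshold resample when `ESS < threshold * K`; set to 1
#'   (or more) to resample every generation, 0 to never resample.
#' @param median_ref frozen reference branch length used by Step 1 L as the
#'   nonzero trial pendant length; when `NULL` it is taken as the median
#'   branch length of the first tree of the initial sample at run start.
#' @return a list of class `opsmc_config`.
#' @export
opsmc_config <- function(prior_rate = 10, pendant_rate = 10, alpha = 0.05,
                         resample_threshold = 0.5, median_ref = NULL) {
  structure(list(prior_rate = prior_rate, pendant_rate = pendant_rate,
                 alpha = alpha, resample_threshold = resample_threshold,
                 median_ref = median_ref),
            class = "opsmc_config")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Heating: exponentiate normalized probabilities, renormalize.  Equivalent
## to exponentiating the raw weights since normalization constants cancel.
heat_probs <- function(probs, alpha) {
  if (alpha == 1) return(probs)
  p <- probs^alpha
  p / sum(p)
}

## ------------------------------ Step 1 -------------------------------------

#' Step 1 U: choose the attachment branch uniformly
#' @param tree a canonical `phylo`.
#' @return list with `edge`, `probs`, `log_q`.
#' @export
step1_uniform <- function(tree) {
  ne <- nrow(tree$edge)
  edge <- sample.int(ne, 1L)
  list(edge = edge, probs = rep(1 / ne, ne), log_q = -log(ne))
}

## Step 1 L probabilities from a context: the new taxon is placed at the
## midpoint of each branch with pendant length 0 and (separately) the frozen
## reference length; the branch weight is the larger of the two likelihoods.
step1_likelihood_probs <- function(ctx, median_ref, alpha) {
  ne <- length(ctx$elen)
  lw <- numeric(ne)
  for (e in seq_len(ne)) {
    mid <- ctx$elen[e] / 2
    l0 <- ctx_attach(ctx, e, mid, 0)[1L]
    l1 <- ctx_attach(ctx, e, mid, median_ref)[1L]
    lw[e] <- max(l0, l1)
  }
  probs <- exp(lw - logsumexp(lw))
  probs <- probs / sum(probs)
  heat_probs(probs, alpha)
}

#' Step 1 L: likelihood-guided attachment branch choice
#'
#' @inheritParams attachment_loglik
#' @param alpha heating exponent (1 = unheated).
#' @param median_ref trial pendant length; defaults to the median branch
#'   length of `tree` when not supplied (in SMC runs it is frozen from the
#'   first tree of the initial sample).
#' @return list with `edge` (drawn), `probs`, `log_q`.
#' @export
step1_likelihood <- function(tree, aln, new_taxon, alpha = 1,
                             median_ref = NULL) {
  ctx <- attach_ctx(tree, aln, new_taxon)
  if (is.null(median_ref)) median_ref <- stats::median(tree$edge.length)
  probs <- step1_likelihood_probs(ctx, median_ref, alpha)
  edge <- sample.int(length(probs), 1L, prob = probs)
  list(edge = edge, probs = probs, log_q = log(probs[edge]))
}

#' Step 1 P: parsimony-guided attachment branch choice
#'
#' @inheritParams step1_likelihood
#' @return list with `edge`, `probs`, `log_q`.
#' @export
step1_parsimony <- function(tree, aln, new_taxon, alpha = 1) {
  S <- attachment_parsimony_scores(tree, aln, new_taxon)
  probs <- heat_probs(parsimony_weights(S), alpha)
  edge <- sample.int(length(probs), 1L, prob = probs)
  list(edge = edge, probs = probs, log_q = log(probs[edge]))
}

## ------------------------------ Step 2 -------------------------------------

## Degenerate branches (|e| <= 1e-8) use a point mass at x = 0 with zero
## log-density contribution, identically across all Step 2 variants.
EDGE_EPS <- 1e-8

#' Step 2 U: uniform attachment position
#' @param elen attachment branch length.
#' @return list with `x`, `log_q`.
#' @export
step2_uniform <- function(elen) {
  if (elen <= EDGE_EPS) return(list(x = 0, log_q = 0))
  list(x = stats::runif(1L, 0, elen), log_q = -log(elen))
}

## draw from Normal(mu, sd) truncated to [0, elen] by inverse CDF
rtruncnorm01 <- function(mu, sd, elen) {
  lo <- stats::pnorm(0, mu, sd); hi <- stats::pnorm(elen, mu, sd)
  if (hi - lo < 1e-14) return(min(max(mu, 0), elen))  # numerically degenerate
  stats::qnorm(stats::runif(1L, lo, hi), mu, sd)
}

dtruncnorm01 <- function(x, mu, sd, elen) {
  mass <- stats::pnorm(elen, mu, sd) - stats::pnorm(0, mu, sd)
  stats::dnorm(x, mu, sd, log = TRUE) - log(mass)
}

#' Step 2 N: truncated normal around the MLE with scale |e|/4
#' @param elen attachment branch length.
#' @param x_mle maximum-likelihood distal length in `[0, elen]`.
#' @return list with `x`, `log_q`.
#' @export
step2_normal <- function(elen, x_mle) {
  if (elen <= EDGE_EPS) return(list(x = 0, log_q = 0))
  sd <- elen / 4
  x <- rtruncnorm01(x_mle, sd, elen)
  x <- min(max(x, 0), elen)
  list(x = x, log_q = dtruncnorm01(x, x_mle, sd, elen))
}

#' Step 2 A: truncated normal with asymptotic scale `I(x_MLE)^{-1/2}`
#'
#' Falls back to the |e|/4 scale when the observed information is
#' non-positive or non-finite (e.g. a boundary maximum).
#'
#' @inheritParams step2_normal
#' @param info observed information `-d2/dx2 logL` at `x_mle`.
#' @return list with `x`, `log_q`.
#' @export
step2_asymptotic <- function(elen, x_mle, info) {
  if (elen <= EDGE_EPS) return(list(x = 0, log_q = 0))
  sd <- if (is.finite(info) && info > 0) info^(-0.5) else elen / 4
  x <- rtruncnorm01(x_mle, sd, elen)
  x <- min(max(x, 0), elen)
  list(x = x, log_q = dtruncnorm01(x, x_mle, sd, elen))
}

## ------------------------------ Step 3 -------------------------------------

#' Step 3 P: pendant length from the exponential prior
#' @param rate exponential rate (default 10).
#' @return list with `y`, `log_q`.
#' @export
step3_prior <- function(rate = 10) {
  y <- stats::rexp(1L, rate)
  list(y = y, log_q = stats::dexp(y, rate, log = TRUE))
}

#' Step 3 M: exponential with mean equal to the pendant-length MLE
#'
#' The MLE is floored at 1e-6 so the rate stays finite when the best pendant
#' length is 0 (e.g. a duplicate sequence).
#'
#' @param y_mle maximum-likelihood pendant branch length.
#' @return list with `y`, `log_q`.
#' @export
step3_ml <- function(y_mle) {
  rate <- 1 / max(y_mle, 1e-6)
  y <- stats::rexp(1L, rate)
  list(y = y, log_q = stats::dexp(y, rate, log = TRUE))
}

## lcfit-based Step 3 from a context: profile the pendant-branch curve at the
## chosen (edge, x), fit the surrogate, and sample from surrogate * prior.
## Falls back to Step 3 M on degenerate curves.
step3_lcfit_ctx <- function(ctx, edge, x, prior_rate) {
  med <- stats::median(ctx$elen)
  ymax <- 20 * med + 1
  o <- stats::optimize(function(y) ctx_attach(ctx, edge, x, y)[1L],
                       interval = c(1e-9, ymax), maximum = TRUE, tol = 1e-8)
  y_ml <- o$maximum
  at0 <- ctx_attach(ctx, edge, x, 0, derivs = TRUE)
  if (at0[1L] > o$objective) y_ml <- 0
  if (y_ml < 1e-6) {
    ## boundary maximum: no interior curve to fit.  To first order the
    ## conditional posterior of y is Exp(prior_rate - dlogL/dy|0) (the
    ## log-likelihood slope at 0 is <= 0 here), which matches the true
    ## decay scale instead of collapsing to a point mass
    g <- at0[4L]
    rate <- prior_rate + max(0, -g)
    y <- stats::rexp(1L, rate)
    return(list(y = y, log_q = stats::dexp(y, rate, log = TRUE),
                fallback = TRUE))
  }
  d <- ctx_attach(ctx, edge, x, y_ml, derivs = TRUE)
  tt <- y_ml * c(0.1, 0.5, 1, 2, 10)
  ll <- vapply(tt, function(t) ctx_attach(ctx, edge, x, t)[1L], numeric(1))
  fit <- lcfit_fit(y_ml, d[5L], data.frame(t = tt, ll = ll))
  if (is.null(fit)) {
    res <- step3_ml(y_ml)
    res$fallback <- TRUE
    return(res)
  }
  sm <- lcfit_sample_pendant(fit, prior_rate, 1L)
  if (is.null(sm)) {
    res <- step3_ml(y_ml)
    res$fallback <- TRUE
    return(res)
  }
  list(y = sm$y, log_q = sm$log_density, fallback = FALSE, fit = fit)
}

#' Step 3 F: pendant length from the lcfit surrogate posterior
#'
#' Profiles the pendant-branch log-likelihood at the chosen attachment
#' `(edge, x)`, fits the four-parameter surrogate by curvature matching plus
#' least squares, and samples from the product of the surrogate and the
#' exponential prior by rejection.  Degenerate curves (boundary maximum,
#' flat profile, failed fit) fall back to Step 3 M at the profiled MLE.
#'
#' @inheritParams attachment_loglik
#' @param prior_rate exponential pendant prior rate.
#' @return list with `y`, `log_q`, `fallback`.
#' @export
step3_lcfit <- function(tree, aln, new_taxon, edge, x, prior_rate = 10) {
  ctx <- attach_ctx(tree, aln, new_taxon)
  step3_lcfit_ctx(ctx, edge, x, prior_rate)
}

## ---------------------------------------------------------------------------
## Composite proposal
## ---------------------------------------------------------------------------

## Internal fast path: all inputs prepared, optional per-tree cache (an
## environment) exploiting path degeneracy -- Step 1 distributions and
## per-edge (x, y) MLEs are identical for identical trees and are computed
## once per distinct tree.
propose_ctx <- function(ctx, kernel, config, cache = NULL) {
  ne <- length(ctx$elen)
  ## Step 1
  if (kernel$step1 == "U") {
    edge <- sample.int(ne, 1L)
    probs <- rep(1 / ne, ne)
  } else {
    probs <- if (!is.null(cache) && !is.null(cache$step1)) cache$step1 else {
      p <- if (kernel$step1 == "L") {
        mref <- config$median_ref
        if (is.null(mref)) mref <- stats::median(ctx$elen)
        step1_likelihood_probs(ctx, mref, kernel$alpha)
      } else {
        heat_probs(parsimony_weights(
          cpp_fitch_attach_ctx(ctx)), kernel$alpha)
      }
      if (!is.null(cache)) cache$step1 <- p
      p
    }
    edge <- sample.int(ne, 1L, prob = probs)
  }
  log_q1 <- log(probs[edge])
  elen <- ctx$elen[edge]
  ## per-edge MLE, computed lazily and cached per distinct tree
  need_opt <- kernel$step2 %in% c("N", "A") || kernel$step3 == "M"
  opt <- NULL
  if (need_opt) {
    key <- paste0("opt", edge)
    opt <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(opt)) {
      opt <- ctx_optimize(ctx, edge)
      if (!is.null(cache)) cache[[key]] <- opt
    }
  }
  ## Step 2
  s2 <- switch(kernel$step2,
               U = step2_uniform(elen),
               N = step2_normal(elen, opt$x_mle),
               A = step2_asymptotic(elen, opt$x_mle, opt$info_x))
  ## Step 3
  s3 <- switch(kernel$step3,
               P = step3_prior(config$pendant_rate),
               M = step3_ml(opt$y_mle),
               F = step3_lcfit_ctx(ctx, edge, s2$x, config$pendant_rate))
  ll <- ctx_attach(ctx, edge, s2$x, s3$y)[1L]
  list(edge = edge, x = s2$x, y = s3$y,
       log_q1 = log_q1, log_q2 = s2$log_q, log_q3 = s3$log_q,
       log_q = log_q1 + s2$log_q + s3$log_q,
       loglik = ll)
}

## parsimony Step 1 scores from an attachment context (reuses the context's
## pattern-compressed states)
cpp_fitch_attach_ctx <- function(ctx) {
  cpp_fitch_attach(ctx$tree$edge, ctx$ntip, ctx$states_tree, ctx$weights,
                   ctx$newstate)
}

#' Draw one attachment proposal for a particle
#'
#' Composes the three proposal steps of the kernel and returns the draw
#' together with its total log proposal density
#' `log Q = log q1 + log q2 + log q3` and the log-likelihood of the augmented
#' tree (computed from cached partials; the attachment branch length is
#' conserved as `x + (|e| - x)`).
#'
#' @inheritParams attachment_loglik
#' @param kernel a kernel code string or the result of [parse_kernel()].
#' @param config an [opsmc_config()].
#' @return an attachment draw: list with `edge`, `x`, `y`, `log_q1..3`,
#'   `log_q`, `loglik`.
#' @export
propose <- function(kernel, tree, aln, new_taxon, config = opsmc_config()) {
  if (is.character(kernel)) kernel <- parse_kernel(kernel, config$alpha)
  ctx <- attach_ctx(tree, aln, new_taxon)
  propose_ctx(ctx, kernel, config)
}
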