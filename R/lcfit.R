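## ---------------------------------------------------------------------------
## Four-parameter surrogate for a single-branch log-likelihood curve:
##   f(c, m, r, b; t) = c log[(1 + e^{-r(t+b)})/2] + m log[(1 - e^{-r(t+b)})/2]
## Ignoring b, this is the log-likelihood of a binary symmetric model on two
## sequences with c constant and m mutated sites at rate r; b truncates the
## left side so curves with finite value at t = 0 can be represented.
## ---------------------------------------------------------------------------

#' Construct lcfit surrogate parameters
#' @param c constant-site weight, `>= 0`.
#' @param m mutated-site weight, `>= 0`.
#' @param r rate, `> 0`.
#' @param b left-truncation offset, `>= 0`.
#' @return an object of class `lcfit`.
#' @export
lcfit_params <- function(c, m, r, b) {
  if (c < 0 || m < 0 || r <= 0 || b < 0)
    stop("lcfit parameters must satisfy c >= 0, m >= 0, r > 0, b >= 0")
  structure(list(c = unname(c), m = unname(m), r = unname(r), b = unname(b)),
            class = "lcfit")
}

#' Evaluate the lcfit surrogate log-likelihood
#'
#' @param p an `lcfit` object.
#' @param t branch length(s), `>= 0`.
#' @return surrogate log-likelihood values; `-Inf` where `m > 0` and
#'   `t + b = 0`.
#' @export
lcfit_eval <- function(p, t) {
  if (any(t < 0)) stop("t must be >= 0")
  u <- exp(-p$r * (t + p$b))
  out <- p$c * (log1p(u) - 0.6931471805599453)
  if (p$m > 0) {
    w <- 1 - u
    if (all(w > 0)) {
      out <- out + p$m * (log(w) - 0.6931471805599453)
    } else {
      mterm <- rep(-Inf, length(u))
      ok <- w > 0
      mterm[ok] <- log(w[ok]) - 0.6931471805599453
      out <- out + p$m * mterm
    }
  }
  out
}

#' Maximum-likelihood branch length of the lcfit surrogate
#'
#' Closed form: `(1/r) log((c+m)/(c-m)) - b`, clipped at 0.  When `c <= m`
#' the curve is nondecreasing with no interior maximum and `Inf` is returned
#' so callers can fall back to another proposal.
#'
#' @param p an `lcfit` object.
#' @return the arg-max of the surrogate (possibly 0 or `Inf`).
#' @export
lcfit_ml_t <- function(p) {
  if (p$c <= p$m) return(Inf)
  if (p$m == 0) return(0)
  max(0, log((p$c + p$m) / (p$c - p$m)) / p$r - p$b)
}

## Second derivative of f at arbitrary t (used by tests and the fit):
## with u = e^{-r(t+b)}:  f'' = r^2 u g'(u) + r^2 u^2 g''(u),
## g'(u) = c/(1+u) - m/(1-u), g''(u) = -c/(1+u)^2 - m/(1-u)^2.
lcfit_d2 <- function(p, t) {
  u <- exp(-p$r * (t + p$b))
  g1 <- p$c / (1 + u) - p$m / (1 - u)
  g2 <- -p$c / (1 + u)^2 - p$m / (1 - u)^2
  p$r^2 * u * g1 + p$r^2 * u^2 * g2
}

## Given (r, b) and the two matching constraints -- the surrogate's ML point
## equals t_ml and its curvature there equals d2 -- c and m have the closed
## form below, reducing the fit to 2 dimensions.
lcfit_cm_from_rb <- function(r, b, t_ml, d2) {
  E <- exp(r * (t_ml + b))
  s <- -d2 * (E^2 - 1) / r^2      # c + m
  d <- s / E                      # c - m
  c(c = (s + d) / 2, m = (s - d) / 2)
}

#' Fit the lcfit surrogate to a sampled log-likelihood curve
#'
#' The surrogate's maximum is pinned to `t_ml` and its second derivative
#' there to `d2`; these two constraints eliminate `(c, m)`, leaving a 2-D
#' least-squares fit over `(r, b)` to the sampled points.
#'
#' @param t_ml maximum-likelihood branch length of the true curve (`> 0`).
#' @param d2 second derivative of the true log-likelihood at `t_ml`
#'   (must be `< 0`).
#' @param samples data.frame with columns `t` and `ll` (at least 4 points
#'   spanning `t_ml`).
#' @return an `lcfit` object, or `NULL` when the curve is degenerate
#'   (non-negative curvature or a flat sample) and no fit is possible.
#' @export
lcfit_fit <- function(t_ml, d2, samples) {
  if (!all(c("t", "ll") %in% names(samples)) || nrow(samples) < 4L)
    stop("need >= 4 (t, ll) sample points")
  if (!is.finite(d2) || d2 >= -1e-12) return(NULL)
  if (!is.finite(t_ml) || t_ml <= 0) return(NULL)
  if (max(samples$ll) - min(samples$ll) < 1e-9) return(NULL)
  ts <- samples$t
  ## only the shape of the curve matters (the surrogate posterior is
  ## normalized), so residuals are taken after removing the additive offset
  lls <- samples$ll - mean(samples$ll)
  log2c <- 0.6931471805599453
  rss <- function(par) {
    r <- exp(par[1L]); b <- exp(par[2L])
    E <- exp(r * (t_ml + b))
    s <- -d2 * (E^2 - 1) / r^2
    d <- s / E
    cc <- (s + d) / 2; m <- (s - d) / 2
    if (!is.finite(cc) || !is.finite(m) || cc < 0 || m < 0) return(1e12)
    u <- exp(-r * (ts + b))
    w <- 1 - u
    if (any(w <= 0)) return(1e12)
    pred <- cc * (log1p(u) - log2c) + m * (log(w) - log2c)
    sum((pred - mean(pred) - lls)^2)
  }
  ## coarse grid start, then Nelder-Mead on (log r, log b)
  grid <- expand.grid(lr = log(c(0.3, 1, 3, 9, 27)),
                      lb = log(c(1e-3, 0.03, 0.3)))
  vals <- apply(grid, 1L, rss)
  st <- as.numeric(grid[which.min(vals), ])
  op <- stats::optim(st, rss, method = "Nelder-Mead",
                     control = list(maxit = 250, reltol = 1e-11))
  ## restart once from the optimum: the refreshed simplex tightens the fit
  ## by several orders of magnitude at little cost
  op <- stats::optim(op$par, rss, method = "Nelder-Mead",
                     control = list(maxit = 250, reltol = 1e-15))
  r <- exp(op$par[1L]); b <- exp(op$par[2L])
  cm <- lcfit_cm_from_rb(r, b, t_ml, d2)
  if (!all(is.finite(cm)) || any(cm < 0) || op$value >= 1e12) return(NULL)
  lcfit_params(cm[1L], cm[2L], r, b)
}

## Truncation point for quadrature and sampling: far enough out that the
## surrogate posterior mass beyond it is negligible in tested regimes.
lcfit_tmax <- function(p, prior_rate) {
  tm <- lcfit_ml_t(p)
  if (!is.finite(tm)) tm <- 0
  max(10 * tm, 10 / prior_rate)
}

## log normalizing constant of exp(f(t) - f*) * dexp(t, prior_rate)
## on [0, tmax], by adaptive quadrature.
lcfit_log_norm <- function(p, prior_rate, tmax, fstar) {
  dens <- function(t) exp(lcfit_eval(p, t) - fstar) * stats::dexp(t, prior_rate)
  q <- tryCatch(stats::integrate(dens, 0, tmax, rel.tol = 1e-8,
                                 subdivisions = 200L),
                error = function(e) NULL)
  if (is.null(q) || q$value <= 0) return(NULL)
  log(q$value)
}

#' Sample a pendant branch length from the lcfit surrogate posterior
#'
#' Draws from the density proportional to `exp(f(t)) * prior(t)` on
#' `[0, T_max]` by rejection sampling with the envelope
#' `exp(f(t*)) * prior(t)`, where the prior is exponential with rate
#' `prior_rate` and `T_max = max(10 t*, 10/prior_rate)`.  The returned log
#' density is normalized by adaptive quadrature so it can enter SMC weights.
#'
#' @param p an `lcfit` object with an interior maximum.
#' @param prior_rate rate of the exponential branch-length prior.
#' @param n number of draws.
#' @return list with `y` (draws), `log_density` (normalized log density at
#'   each draw), and `log_norm` (the log normalizing constant); or `NULL` on
#'   quadrature/envelope failure.
#' @export
lcfit_sample_pendant <- function(p, prior_rate, n = 1L) {
  tstar <- lcfit_ml_t(p)
  if (!is.finite(tstar)) return(NULL)
  fstar <- lcfit_eval(p, tstar)
  tmax <- lcfit_tmax(p, prior_rate)
  ln <- lcfit_log_norm(p, prior_rate, tmax, fstar)
  if (is.null(ln)) return(NULL)
  y <- numeric(n)
  got <- 0L
  for (round in seq_len(2000L)) {
    m <- max(64L, 2L * (n - got))
    t <- stats::rexp(m, prior_rate)
    acc <- t <= tmax & log(stats::runif(m)) <= lcfit_eval(p, t) - fstar
    t <- t[acc]
    if (length(t)) {
      take <- min(length(t), n - got)
      y[got + seq_len(take)] <- t[seq_len(take)]
      got <- got + take
    }
    if (got == n) break
  }
  if (got < n) return(NULL)
  logd <- lcfit_eval(p, y) - fstar + stats::dexp(y, prior_rate, log = TRUE) - ln
  list(y = y, log_density = logd, log_norm = ln)
}

## Normalized log density of the surrogate posterior at y (same truncation
## and normalization as lcfit_sample_pendant).
lcfit_log_density <- function(p, prior_rate, y) {
  tstar <- lcfit_ml_t(p)
  fstar <- lcfit_eval(p, tstar)
  tmax <- lcfit_tmax(p, prior_rate)
  ln <- lcfit_log_norm(p, prior_rate, tmax, fstar)
  if (is.null(ln)) return(NULL)
  ifelse(y <= tmax,
         lcfit_eval(p, y) - fstar + stats::dexp(y, prior_rate, log = TRUE) - ln,
         -Inf)
}
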