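---
title: "Online phylogenetic SMC with guided attachment proposals: models and methods"
author: "opsmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online phylogenetic SMC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bayesian phylogenetic inference ordinarily treats the alignment as fixed:
when a new sequence arrives (as happens continuously in outbreak
surveillance), the whole MCMC analysis must be restarted.  `opsmc`
implements *online* inference by sequential Monte Carlo (SMC): an existing
posterior sample of unrooted trees is treated as a particle population, and
each arriving taxon is grafted onto every particle by a proposal kernel,
after which importance weights restore the correct posterior on the enlarged
taxon set.

## Model

Data are aligned nucleotide sequences; sites are independent and identically
distributed, and substitution follows the Jukes–Cantor (JC69) model, whose
transition probabilities have the closed form
$p_\text{same}(t) = \tfrac14 + \tfrac34 e^{-4t/3}$,
$p_\text{diff}(t) = \tfrac14 - \tfrac14 e^{-4t/3}$.
The state is an unrooted binary topology $\tau$ with branch lengths
$l = (l_1,\dots,l_{2N-3})$; the prior is uniform on topologies and
i.i.d. exponential with mean 0.1 (rate 10) on branch lengths.  The
unnormalized posterior is $\hat\pi(\tau,l) = P(\psi\mid\tau,l)\,\pi(\tau,l)$,
with the likelihood computed by Felsenstein pruning (in compiled code, with
per-pattern scaling; alignment columns are compressed to unique site
patterns).  Trees carry an arbitrary traversal root; every computed quantity
is invariant to it, and "distal" always means the root-far side of a branch.

## The SMC update

At generation $n$ each particle is a tree on the current taxon set with a
normalized weight.  One generation inserts one taxon:

1. **Resample** (stratified) when $\mathrm{ESS} < 0.5\,K$ (configurable;
   $\mathrm{ESS} = (\sum w)^2/\sum w^2$), using the previous generation's
   weights.
2. **Mutate**: each particle receives an attachment draw
   $(e, x, y)$ — branch, distal position, pendant length — from the kernel
   $Q$, and becomes a tree with one more leaf.  The attachment branch's
   length is conserved ($x$ plus $|e|-x$).
3. **Reweight**: $\tilde w_i \propto w_i\,
   \hat\pi_{n+1}(t_i') / [\hat\pi_n(t_i)\, Q(t_i \to t_i')]$.

The uniform-topology prior constants are particle-independent within a
generation and are dropped; consequently the running normalizing-constant
trace (`log_z`) omits them as well.  The reported per-generation ESS is that
of the fresh weights, before any later resampling.  The particle count is
held constant across generations.

A single seeded RNG stream drives the whole run.  Per-distinct-tree caches
(keyed by lineage id: particles copied by resampling share their ancestor's
id) store the Step 1 distribution and per-branch attachment optima, which is
the path-degeneracy reuse that makes guided kernels affordable; cache
lookups consume no randomness, so caching cannot change the draws.

## The three-step proposal family

Kernels are three-letter codes (e.g. `LAF`, `~UUP`); a leading `~` marks the
unheated Step 1 variant.

**Step 1 — attachment branch.**
`U`: uniform over the $2n-3$ branches.
`L`: the taxon is tentatively attached at each branch midpoint with pendant
length 0 and, separately, a frozen reference length (the median branch
length of the first initial tree); the branch weight is the larger of the
two likelihoods.
`P`: weights $\exp(\min(S) - s_i)$ from first-pass Fitch parsimony scores
$s_i$ of attaching to branch $i$ (computed for all branches at once from
shared inside/outside state-set caches).
Heated variants raise the normalized probabilities to $\alpha = 0.05$ and
renormalize (equivalent to heating the raw weights); heating repairs the
proposal-collapse pathology of unheated likelihood guidance, where one
branch can take essentially all proposal mass while the posterior is less
concentrated.

**Step 2 — distal position** on the chosen branch.
`U`: uniform on $[0, |e|]$.
`N`: normal truncated to $[0,|e|]$, centered at the maximum-likelihood
distal length with scale $|e|/4$.
`A`: as `N` but with asymptotic scale $I(x_\text{MLE})^{-1/2}$ from the
analytic observed information; if the information is non-positive (boundary
optimum) the $|e|/4$ scale is used.
Branches shorter than $10^{-8}$ use a point mass at $x=0$ with zero
log-density, identically across variants, so weights stay well defined.

**Step 3 — pendant length.**
`P`: the Exp(10) prior.
`M`: exponential with mean equal to the pendant MLE (floored at $10^{-6}$).
`F`: the lcfit surrogate (below) fitted to the pendant profile at the chosen
$(e,x)$, then a draw from surrogate $\times$ prior by rejection sampling.

The total proposal density is the product of the three step densities, each
properly normalized.  The $(x,y)$ maximum-likelihood attachment needed by
`N`/`A`/`M` is found by coordinate-wise Brent searches (tolerance $10^{-8}$,
stopped when a round improves the joint log-likelihood by less than
$10^{-6}$, at most 20 rounds); derivatives and the observed information come
from analytic first/second derivatives of the pruning likelihood in a single
branch length.  Whether the original method optimized $(x,y)$ jointly or
coordinate-wise is not specified anywhere we could find; coordinate-wise is
documented here as this package's choice.

## The lcfit surrogate

The pendant-branch log-likelihood curve is approximated by
$f(c,m,r,b;t) = c\log[(1+e^{-r(t+b)})/2] + m\log[(1-e^{-r(t+b)})/2]$,
the two-state symmetric-model log-likelihood of $c$ constant and $m$ mutated
sites at rate $r$, left-truncated by $b$.  Closed forms used throughout:
the maximizer $t^\* = \tfrac1r \log\frac{c+m}{c-m} - b$ (clipped at 0;
no interior maximum when $c \le m$) and the curvature
$f''(t^\*) = -r^2 (c-m)^2 (c+m) / (4cm)$.

Fitting pins $t^\*$ to the profiled MLE and $f''(t^\*)$ to the analytic
second derivative; solving these two constraints for $(c,m)$ given $(r,b)$
leaves a 2-D least-squares problem over $(r,b)$, optimized by Nelder–Mead
from a coarse grid (with one restart to polish).  Because the surrogate is a
two-state model it can match a four-state JC69 curve only up to an additive
constant, so residuals are taken on mean-centered curves — the normalized
surrogate posterior, which is all the sampler uses, is unaffected.  With the
curvature constraint the best attainable accuracy on $[t^\*/4, 4t^\*]$ for a
1000-site JC69 curve is about 0.06 log units (the unconstrained family
reaches 0.026); the tests assert 0.1.

Sampling uses rejection from the prior envelope $e^{f(t^\*)}\cdot\text{prior}$,
truncated at $T_\max = \max(10\,t^\*, 10/\lambda_\text{prior})$, and the
returned density is normalized by adaptive quadrature on $[0, T_\max]$ so it
can enter SMC weights.  Degenerate profiles fall back gracefully: a flat or
non-concave curve falls back to the `M` proposal at the profiled MLE, and a
*boundary* maximum ($y^\* \approx 0$, e.g. a near-duplicate sequence) uses
$\text{Exp}(\lambda_\text{prior} - \partial_y \log L|_0)$, the first-order
approximation of the true conditional posterior.  The boundary case matters:
an exponential with mean $10^{-6}$ (the literal `M` fallback) is so much
narrower than the true posterior that single tail draws receive enormous
importance weights and can collapse the ESS of an otherwise healthy run.

## Reference MCMC

A Metropolis–Hastings sampler over $(\tau, l)$ targets the same
unnormalized posterior and stands in for an external MCMC package both as
the source of initial posterior samples and as the independent full-data
reference for diagnostics.  Moves: NNI (probability 0.4), a branch-length
multiplier with log-window 2 (0.5), and leaf SPR — prune a leaf, merge the
flanking branches, regraft uniformly on a branch at a uniform position with
the Hastings ratio $|e_\text{target}|/|e_\text{merged}|$ (0.1).  Defaults
follow the benchmark protocol: 300{,}000 iterations thinned to 1000 recorded
samples with the first 250 discarded (750 trees).  Low NNI/SPR acceptance
rates (~1–2%) are expected on peaked 1000-site posteriors; prior-only mode
(`likelihood = FALSE`) is used in tests to verify the sampler recovers the
exponential branch prior and the uniform topology distribution exactly.

## Synthetic benchmarks

`make_benchmark()` reproduces the study conditions: birth–death trees
($\lambda = 6$, $\mu = 2$) conditioned on $N \in \{10, 50, 100\}$ extant
tips by forward simulation (retrying on extinction, stopping at the first
moment $N$ lineages coexist), JC69 alignments of 1000 sites, and 1, 3 or 5
held-out taxa chosen uniformly at random (or given explicitly).  Because no
clock rate mapping time to substitutions is part of those conditions, each
tree is rescaled so its median branch length is 0.05 expected substitutions
— informative but unsaturated at 1000 sites.  The generator emulates the
shape and information content of the benchmark data, not features of real
sequence data such as rate heterogeneity, indel structure, or alignment
error; passing benchmarks therefore demonstrates correctness of the sampler
under its own model, not robustness to model violation.

## Diagnostics

Split (bipartition) frequencies are computed from weighted particles
directly, without resampling.  `asdsf()` follows the MrBayes convention:
splits reaching frequency 0.1 in at least one run contribute the two-run
sample standard deviation ($n-1$ denominator, i.e. $|f_1-f_2|/\sqrt2$), and
ASDSF $< 0.01$ is the usual convergence rule.  `weighted_rf()` is the L1
branch-score distance over the union of splits including pendant branches.
Because the benchmark's generating tree is known, tree-distance diagnostics
compare against the simulated truth rather than an externally estimated ML
tree.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline at the
sizes this package treats as its reference desk scale: 10-taxon, 1000-site
benchmarks with one held-out taxon; reference chains of 150k (tests) or 300k
(acceptance script) iterations thinned to 750 retained trees; SMC particle
factors 1–10.  The guided-vs-unguided contrast uses the same benchmark with
five sequentially inserted taxa — a single easy insertion cannot separate
the kernels when the posterior is nearly certain — comparing the unguided
kernel at factor 1 on the full 750-tree reference (averaged over three
seeds, since its collapsed particle population makes single runs noisy)
against the guided kernel at factor 100 on a 15-tree subsample.  The 4-taxon oracle check integrates branch
lengths by importance sampling from the prior ($10^5$ draws) against an
exhaustive topology enumeration, and agreement is asserted within 3 combined
Monte Carlo standard errors, with the SMC standard error taken as
$\sqrt{\hat p(1-\hat p)/\mathrm{ESS}}$.  Unheated likelihood kernels
(`~L**`) are excluded from that assertion: they exhibit the documented
pathology in which the proposal concentrates on one branch, the ESS is high,
and the estimate is biased — the behavior that motivates heating in the
first place.

Other numerical choices: per-pattern likelihood rescaling triggers below
$10^{-100}$; tip ambiguity codes map to state-set indicator vectors and
gaps/`?` to all-ones; Newick output keeps 17 significant digits so
write/parse round-trips are exact; ties in parsimony weights need no
tie-breaking (the weight formula is already symmetric).

## Limitations

JC69 only, unrooted non-clock trees only, pure SMC (no rejuvenating MCMC
moves between generations), constant particle counts, and single-threaded
execution.  Sequences whose attachment would introduce branches much longer
than those already present violate the assumptions under which online SMC
tracks the posterior and can degrade the approximation; the ESS trace is the
first diagnostic to consult.
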