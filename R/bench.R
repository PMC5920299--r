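## ---------------------------------------------------------------------------
## End-to-end benchmark driver: simulate -> reference MCMC on the reduced
## data -> online SMC -> independent reference MCMC on the full data ->
## split diagnostics.  Produces one tidy row per (kernel, particle factor,
## seed) cell.
## ---------------------------------------------------------------------------

#' Run one simulated online-inference benchmark cell
#'
#' @param bench a benchmark from [make_benchmark()].
#' @param kernel kernel code string.
#' @param particle_factor particles per initial tree.
#' @param seed seed for the SMC run.
#' @param init_trees reduced-data posterior sample (from [mcmc_sample()] on
#'   the retained taxa).
#' @param ref_trees independent full-data posterior sample.
#' @param config an [opsmc_config()].
#' @return one-row data.frame with ESS, ASDSF, split-difference summaries and
#'   weighted RF to the true tree.
#' @export
benchmark_cell <- function(bench, kernel, particle_factor, seed,
                           init_trees, ref_trees, config = opsmc_config()) {
  t0 <- proc.time()[["elapsed"]]
  sys <- run_online(init_trees, bench$aln, bench$holdout, kernel,
                    particle_factor, config, seed = seed)
  wall <- proc.time()[["elapsed"]] - t0
  sd_ <- split_abs_diff(split_frequencies(sys$trees, sys$weights),
                        split_frequencies(ref_trees))
  as_ <- asdsf(sys$trees, ref_trees, weights_a = sys$weights)
  map_idx <- which.max(sys$weights)
  wrf <- weighted_rf(sys$trees[[map_idx]],
                     canonical_tree(bench$true_tree))
  data.frame(label = bench$manifest$label, kernel = kernel,
             factor = particle_factor, seed = seed,
             ess = tail(sys$ess_trace, 1L),
             mean_ess = mean(sys$ess_trace),
             asdsf = as_, mean_absdiff = sd_$mean, sd_absdiff = sd_$sd,
             wrf_true = wrf, wall_s = wall)
}

#' Grid benchmark over kernels, particle factors and seeds
#'
#' Reproduces the study design at configurable scale: for each cell the
#' held-out taxa are inserted online into a reduced-data reference posterior
#' and the result is compared to an independent full-data reference
#' posterior.  Failures in a cell are recorded, not fatal.
#'
#' @param bench a benchmark from [make_benchmark()].
#' @param kernels character vector of kernel codes.
#' @param particle_factors integer vector.
#' @param seeds integer vector of SMC seeds.
#' @param mcmc an [mcmc_config()] for the two reference runs.
#' @param config an [opsmc_config()].
#' @param mcmc_seed seed for the reference runs.
#' @return data.frame with one row per (kernel, factor, seed) cell.
#' @export
benchmark_driver <- function(bench, kernels = c("~UUP", "LAF", "PAF"),
                             particle_factors = c(1L, 5L, 10L),
                             seeds = 1L, mcmc = mcmc_config(),
                             config = opsmc_config(), mcmc_seed = 101L) {
  red <- bench$aln[bench$retained]
  init <- mcmc_sample(red, mcmc, seed = mcmc_seed)$trees
  ref <- mcmc_sample(bench$aln, mcmc, seed = mcmc_seed + 1L)$trees
  rows <- list()
  for (k in kernels) for (f in particle_factors) for (s in seeds) {
    row <- tryCatch(
      benchmark_cell(bench, k, f, s, init, ref, config),
      error = function(e)
        data.frame(label = bench$manifest$label, kernel = k, factor = f,
                   seed = s, ess = NA, mean_ess = NA, asdsf = NA,
                   mean_absdiff = NA, sd_absdiff = NA, wrf_true = NA,
                   wall_s = NA))
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
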