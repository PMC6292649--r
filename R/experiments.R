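#' Matched passive/active noise experiment
#'
#' Runs the package's standard active-noise comparison at configurable
#' scale: for each replicate, generate a fresh synthetic annotation with the
#' target active fraction, collapse one extended chain into a crumpled
#' globule, then run a passive and an active Brownian trajectory from the
#' same structure with the same noise seed (the active run doubles the
#' noise variance on A-type loci). Reported per replicate: the percent
#' increase of the A1 loci-averaged MSD at the given lags, and the
#' loci-averaged diffusion exponents of both runs.
#'
#' @param n_loci chain length (default 256).
#' @param n_replicates independent replicates (fresh annotation each).
#' @param t_total length of each run (tau_BD).
#' @param lags comparison lags (tau_BD), inside the subdiffusive window.
#' @param seed master seed; every stage derives its own sub-seed.
#' @param mean_block_len,n_loops,target_active annotation settings.
#' @param exponent_window lag window for the exponent fits.
#' @param variance_multiplier active noise variance multiplier (default 2).
#' @return data.frame with one row per replicate: `pct_increase`,
#'   `beta_passive`, `beta_active`, `active_fraction`.
#' @export
active_msd_experiment <- function(n_loci = 256, n_replicates = 3,
                                  t_total = 400,
                                  lags = c(10, 15, 20, 30, 40, 50),
                                  seed = 1L, mean_block_len = 20,
                                  n_loops = 20, target_active = 0.4,
                                  exponent_window = c(30, 200),
                                  variance_multiplier = 2) {
  out <- lapply(seq_len(n_replicates), function(r) {
    base <- seed * 131L + r * 17L
    ann <- generate_annotation(n_loci, mean_block_len, seed = base,
                               target_active = target_active)
    ann <- generate_loops(ann, n_loops, 10, min(80, n_loci - 1),
                          seed = base + 1L)
    par <- chrom_params(n_loci)
    rw <- make_rouse_ensemble(n_loci, 1, 1, seed = base + 2L)[[1]]
    init <- langevin_sample(rw, ann, par, n_samples = 1, spacing = 1,
                            burn_in = 40, seed = base + 3L)[[1]]
    prof <- make_activity_profile(
      ann, activity_spec(variance_multiplier = variance_multiplier))
    trp <- brownian_run(init, ann, par, t_total = t_total, dt = 1e-3,
                        frame_interval = 0.25, seed = base + 4L)
    tra <- brownian_run(init, ann, par, activity_profile = prof,
                        t_total = t_total, dt = 1e-3, frame_interval = 0.25,
                        seed = base + 4L)
    mp <- msd_aggregate(trp, "A1", lags = lags, annotation = ann)
    ma <- msd_aggregate(tra, "A1", lags = lags, annotation = ann)
    data.frame(
      replicate = r,
      pct_increase = 100 * (mean(ma$value / mp$value) - 1),
      beta_passive = fit_diffusion_exponent(msd_aggregate(trp, "all"),
                                            exponent_window)$beta,
      beta_active = fit_diffusion_exponent(msd_aggregate(tra, "all"),
                                           exponent_window)$beta,
      active_fraction = active_fraction(ann))
  })
  do.call(rbind, out)
}

#' Crumpled-globule structural ensemble
#'
#' The package's standard structure-generation protocol: `n_samples`
#' independent collapses of extended chains under the heteropolymer
#' potential (one conformation per collapse), which freezes in space-filling
#' statistics.
#'
#' @param annotation a [chrom_annotation].
#' @param params a [chrom_params].
#' @param n_samples ensemble size.
#' @param seed master seed.
#' @param burn_in collapse time per chain (Langevin time units).
#' @return List of N x 3 conformations.
#' @export
collapse_conformations <- function(annotation, params, n_samples = 50,
                                   seed = 1L, burn_in = 40) {
  N <- annotation$n_loci
  lapply(seq_len(n_samples), function(k) {
    rw <- make_rouse_ensemble(N, 1, 1, seed = seed * 131L + 7000L + k)[[1]]
    langevin_sample(rw, annotation, params, n_samples = 1, spacing = 1,
                    burn_in = burn_in, seed = seed * 131L + 100L + k)[[1]]
  })
}
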