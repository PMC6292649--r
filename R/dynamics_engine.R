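#' Active-noise specification
#'
#' Loci whose subcompartment label is in `active_labels` receive white noise
#' with `variance_multiplier` times the passive variance (6 D0 -> 12 D0 per
#' unit time at the default multiplier 2), breaking fluctuation-dissipation
#' on active loci only; the mobility (drift response) is unchanged.
#'
#' @param active_labels subset of [chrom_types] (default A1, A2).
#' @param variance_multiplier positive noise-variance multiplier (default 2).
#' @export
activity_spec <- function(active_labels = c("A1", "A2"),
                          variance_multiplier = 2) {
  bad <- setdiff(active_labels, chrom_types)
  if (length(bad) > 0)
    stop("unknown label(s) in activity spec: ", paste(bad, collapse = ", "))
  stopifnot_scalar(variance_multiplier, "variance_multiplier", positive = TRUE)
  structure(list(active_labels = active_labels,
                 variance_multiplier = variance_multiplier),
            class = "activity_spec")
}

#' Per-locus noise-variance multipliers
#'
#' @param annotation a [chrom_annotation].
#' @param spec an [activity_spec].
#' @return Numeric vector of length N: `variance_multiplier` on active loci,
#'   1 elsewhere.
#' @export
make_activity_profile <- function(annotation, spec = activity_spec()) {
  stopifnot(inherits(annotation, "chrom_annotation"))
  if (!inherits(spec, "activity_spec")) stop("spec must be an activity_spec")
  ifelse(annotation$labels %in% spec$active_labels,
         spec$variance_multiplier, 1)
}

new_trajectory <- function(frames, frame_interval, dt, seed,
                           activity_profile, n_flagged = 0L, n_rejected = 0L) {
  structure(list(frames = frames, frame_interval = frame_interval, dt = dt,
                 seed = seed, activity_profile = activity_profile,
                 n_flagged = n_flagged, n_rejected = n_rejected),
            class = "chrom_trajectory")
}

#' @export
print.chrom_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat("<chrom_trajectory> ", d[1], " frames x ", d[2], " loci, ",
      "frame_interval = ", x$frame_interval, " tau_BD, dt = ", x$dt,
      ", seed = ", x$seed, "\n", sep = "")
  if (any(x$activity_profile != 1))
    cat("  active loci: ", sum(x$activity_profile != 1), " (multiplier ",
        max(x$activity_profile), ")\n", sep = "")
  invisible(x)
}

#' Number of frames / loci of a trajectory
#' @param traj a `chrom_trajectory`
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' @rdname n_frames
#' @export
n_loci <- function(traj) dim(traj$frames)[2]

#' Extract one frame as a conformation matrix
#' @param traj a `chrom_trajectory`
#' @param t frame index (1-based)
#' @export
frame_at <- function(traj, t) {
  f <- traj$frames[t, , , drop = FALSE]
  dim(f) <- dim(traj$frames)[2:3]
  f
}

# stability cap for the overdamped integrator: the stiffest harmonic term
# must decay, with margin, under Euler-Maruyama
bd_dt_cap <- function(params) {
  kmax <- max(params$bond_k, params$ev_k, params$wall_k, 1)
  0.5 / kmax
}

#' Conformational sampling by low-friction Langevin dynamics
#'
#' Underdamped BAOAB integration at k_BT = 1, m = 1 with friction
#' `friction` (1/tau_BD). Used to collapse extended chains and harvest
#' decorrelated conformations after a burn-in phase; the low friction makes
#' barrier crossing (conformational search) fast compared to the overdamped
#' production dynamics.
#'
#' @param initial N x 3 starting coordinates.
#' @param annotation a [chrom_annotation].
#' @param params a [chrom_params].
#' @param n_samples number of conformations to return.
#' @param spacing time between samples (tau-like Langevin time units).
#' @param friction Langevin friction coefficient (default 0.1).
#' @param seed integer seed (trajectory is bit-reproducible given all inputs).
#' @param dt integration step.
#' @param burn_in collapse/equilibration time before the first sample.
#' @param return_velocities also return velocities (for diagnostics).
#' @return List of N x 3 matrices (or list with `samples` and `velocities`).
#' @export
langevin_sample <- function(initial, annotation, params,
                            n_samples = 50L, spacing = 10,
                            friction = 0.1, seed = 1L,
                            dt = 0.01, burn_in = 100,
                            return_velocities = FALSE) {
  stopifnot_scalar(friction, "friction", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  a <- cpp_args(initial, annotation, params)
  names(a)[names(a) == "coords"] <- "coords0"
  a$n_samples <- as.integer(n_samples)
  a$spacing_steps <- max(1L, as.integer(round(spacing / dt)))
  a$burnin_steps <- as.integer(round(burn_in / dt))
  a$dt <- dt
  a$friction <- friction
  a$seed <- as.double(seed)
  a$f_clamp <- 1e3
  a$v_clamp <- 5
  a$nl_every <- 5L
  a$nl_skin <- 0.8
  a$return_velocities <- isTRUE(return_velocities)
  out <- do.call(cpp_langevin_sample, a)
  if (isTRUE(return_velocities)) out else out$samples
}

#' Production Brownian dynamics with optional active noise
#'
#' Overdamped Euler-Maruyama update
#' `r_i <- r_i + F_i dt + xi_i`, with `xi_i` zero-mean Gaussian of
#' per-component variance `2 multiplier_i dt` in reduced units (D0 = a^2 /
#' tau_BD = 1, k_BT = 1), so a single free passive bead has MSD = 6 t. The
#' deterministic drift per bead and step is capped at `cap_drift`
#' (operational chain non-crossing guard together with the excluded-volume
#' repulsion); steps whose total per-bead displacement would exceed
#' `cap_reject` are redrawn and counted.
#'
#' @param initial N x 3 starting coordinates.
#' @param annotation a [chrom_annotation].
#' @param params a [chrom_params].
#' @param activity_profile per-locus noise-variance multipliers
#'   (default all 1 = passive); see [make_activity_profile()].
#' @param t_total total simulated time (tau_BD).
#' @param dt time step (tau_BD); must not exceed the stability cap
#'   0.5 / max(stiffness).
#' @param frame_interval time between stored frames; must be a multiple of dt.
#' @param seed integer seed.
#' @param cap_drift per-step drift displacement cap (a).
#' @param cap_reject hard bound on total per-step displacement (a).
#' @param nl_every,nl_skin neighbour-list rebuild cadence (steps) and skin
#'   width (a); affect speed only, not the force law.
#' @return A `chrom_trajectory` with frames array (T x N x 3) including the
#'   initial conformation as frame 1.
#' @export
brownian_run <- function(initial, annotation, params,
                         activity_profile = NULL,
                         t_total, dt = 1e-3, frame_interval = 1,
                         seed = 1L, cap_drift = 0.1, cap_reject = 0.5,
                         nl_every = 10L, nl_skin = 1.0) {
  stopifnot_scalar(t_total, "t_total", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  cap <- bd_dt_cap(params)
  if (dt > cap + 1e-15)
    stop("dt = ", dt, " exceeds the stability cap ", cap,
         " for the stiffest configured term")
  stride <- frame_interval / dt
  if (abs(stride - round(stride)) > 1e-8)
    stop("frame_interval must be a multiple of dt")
  stride <- as.integer(round(stride))
  n_steps <- as.integer(round(t_total / dt))
  if (n_steps < stride) stop("t_total shorter than one frame_interval")
  n <- annotation$n_loci
  if (is.null(activity_profile)) activity_profile <- rep(1, n)
  if (length(activity_profile) != n || any(activity_profile < 0))
    stop("activity_profile must be N nonnegative multipliers")
  a <- cpp_args(initial, annotation, params)
  names(a)[names(a) == "coords"] <- "coords0"
  a$mult <- as.double(activity_profile)
  a$n_steps <- (n_steps %/% stride) * stride
  a$dt <- dt
  a$stride <- stride
  a$seed <- as.double(seed)
  a$cap_drift <- cap_drift
  a$cap_reject <- cap_reject
  a$nl_every <- as.integer(nl_every)
  a$nl_skin <- nl_skin
  out <- do.call(cpp_brownian_run, a)
  new_trajectory(out$frames, frame_interval = frame_interval, dt = dt,
                 seed = seed, activity_profile = activity_profile,
                 n_flagged = out$n_flagged, n_rejected = out$n_rejected)
}
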