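#' Default log-spaced lag grid for a trajectory
#'
#' About `per_decade` lags per decade on the frame grid, deduplicated, which
#' keeps log-log exponent fits well conditioned.
#'
#' @param traj a `chrom_trajectory`.
#' @param per_decade lags per decade.
#' @param max_fraction largest lag as a fraction of the trajectory length
#'   (keeps enough time origins for the time average).
#' @return Numeric vector of lag times (tau_BD).
#' @export
log_lags <- function(traj, per_decade = 30, max_fraction = 0.5) {
  T <- n_frames(traj)
  lmax <- floor((T - 1) * max_fraction)
  if (lmax < 1) stop("trajectory too short for lags")
  lf <- unique(round(10^(seq(0, log10(lmax), by = 1 / per_decade))))
  lf[lf >= 1 & lf <= lmax] * traj$frame_interval
}

# lags (time) -> frame offsets, validated
lag_frames <- function(traj, lags) {
  L <- lags / traj$frame_interval
  if (any(abs(L - round(L)) > 1e-8))
    stop("lags must be multiples of frame_interval")
  L <- as.integer(round(L))
  if (any(L < 0) || any(L >= n_frames(traj)))
    stop("lags must lie within the trajectory")
  L
}

# core: mean squared displacement averaged over all admissible time origins
# on the frame grid, per locus subset; returns one value per lag
msd_core <- function(frames, L_frames, idx) {
  T <- dim(frames)[1]
  vapply(L_frames, function(L) {
    if (L == 0) return(0)
    d <- frames[seq.int(1 + L, T), idx, , drop = FALSE] -
      frames[seq_len(T - L), idx, , drop = FALSE]
    sum(d^2) / ((T - L) * length(idx))
  }, numeric(1))
}

new_msd_curve <- function(lags, values, n_t0, scope) {
  out <- data.frame(lag = lags, value = values, n_t0 = n_t0)
  out <- out[order(out$lag), ]
  rownames(out) <- NULL
  attr(out, "scope") <- scope
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Time-averaged MSD of a single locus
#'
#' `MSD_i(t) = < |r_i(t0 + t) - r_i(t0)|^2 >_t0`, the time origin running
#' over every frame with `t0 + t` inside the trajectory.
#'
#' @param traj a `chrom_trajectory`.
#' @param i locus index (1-based).
#' @param lags lag times (tau_BD, multiples of the frame interval);
#'   default [log_lags()].
#' @return data.frame of class `msd_curve` with `lag`, `value` (a^2) and
#'   `n_t0` (number of time origins).
#' @export
msd_locus <- function(traj, i, lags = log_lags(traj)) {
  N <- n_loci(traj)
  if (length(i) != 1 || i < 1 || i > N) stop("locus index out of range")
  L <- lag_frames(traj, lags)
  v <- msd_core(traj$frames, L, as.integer(i))
  new_msd_curve(lags, v, n_frames(traj) - L, paste0("locus_", i))
}

#' Aggregate time-averaged MSD
#'
#' `selection` chooses the averaging scope: `"all"` (loci-averaged MSD,
#' the mean of the per-locus curves), `"com"` (MSD of the chain's centre of
#' mass), `"midpoint"` (locus N/2), a character vector of subcompartment
#' labels (requires `annotation`), or an integer vector of locus indices.
#'
#' @param traj a `chrom_trajectory`.
#' @param selection scope (see above).
#' @param lags lag times.
#' @param annotation needed when `selection` is a label set.
#' @return An `msd_curve`.
#' @export
msd_aggregate <- function(traj, selection = "all", lags = log_lags(traj),
                          annotation = NULL) {
  N <- n_loci(traj)
  L <- lag_frames(traj, lags)
  if (is.character(selection) && length(selection) == 1 &&
      selection %in% c("all", "com", "midpoint")) {
    if (selection == "com") {
      T <- dim(traj$frames)[1]
      com <- apply(traj$frames, c(1, 3), mean) # T x 3
      v <- vapply(L, function(l) {
        if (l == 0) return(0)
        d <- com[seq.int(1 + l, T), , drop = FALSE] -
          com[seq_len(T - l), , drop = FALSE]
        sum(d^2) / (T - l)
      }, numeric(1))
      return(new_msd_curve(lags, v, T - L, "com"))
    }
    idx <- if (selection == "all") seq_len(N) else as.integer(round(N / 2))
    scope <- selection
  } else if (is.character(selection)) {
    if (is.null(annotation)) stop("label selection needs an annotation")
    idx <- which(annotation$labels %in% selection)
    if (length(idx) == 0) stop("no loci with the requested labels")
    scope <- paste(selection, collapse = "+")
  } else {
    idx <- as.integer(selection)
    if (any(idx < 1 | idx > N)) stop("locus indices out of range")
    scope <- "subset"
  }
  v <- msd_core(traj$frames, L, idx)
  new_msd_curve(lags, v, n_frames(traj) - L, scope)
}

#' Diffusion exponent from a log-log fit of an MSD curve
#'
#' Fits `MSD = C t^beta` by unweighted least squares in log-log space within
#' the stated lag window.
#'
#' @param curve an `msd_curve` (or data.frame with `lag`, `value`).
#' @param window inclusive lag range to fit (>= 3 points required).
#' @return List with `beta` and `C`.
#' @export
fit_diffusion_exponent <- function(curve, window) {
  f <- fit_power_law(curve$lag, curve$value, window)
  list(beta = f$exponent, C = f$prefactor, n_points = f$n_points)
}

#' Offset-power-law fit MSD = A + B t^beta
#'
#' Nonlinear least squares of the three-parameter model `A + B t^beta'`
#' (used for displacement data with a static offset). If the power-law
#' amplitude is negligible the exponent is unidentifiable and flagged.
#'
#' @param curve an `msd_curve`-like data.frame.
#' @param window inclusive lag range (default: all positive lags).
#' @return List with `A`, `B`, `beta`, and `identifiable`.
#' @export
fit_offset_power <- function(curve, window = NULL) {
  d <- curve[curve$lag > 0, , drop = FALSE]
  if (!is.null(window)) d <- d[d$lag >= window[1] & d$lag <= window[2], ]
  if (nrow(d) < 4) stop("need at least 4 points to fit A + B t^beta")
  # starting values: pure power on the upper half, offset from the low end
  up <- d[d$lag >= stats::median(d$lag), ]
  st <- tryCatch(fit_power_law(up$lag, pmax(up$value - min(d$value) * 0.5,
                                            .Machine$double.eps), range(up$lag)),
                 error = function(e) list(exponent = 0.5,
                                          prefactor = max(d$value) /
                                            max(d$lag)^0.5))
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ A + B * lag^beta, data = d,
                      start = list(A = min(d$value) * 0.5,
                                   B = st$prefactor,
                                   beta = min(max(st$exponent, 0.05), 1.95)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("offset-power fit did not converge")
  p <- as.list(coef(fit))
  scale <- max(abs(d$value))
  identifiable <- abs(p$B) * max(d$lag)^p$beta > 1e-6 * scale
  list(A = p$A, B = p$B, beta = if (identifiable) p$beta else NA_real_,
       identifiable = identifiable)
}

#' Structural deviation delta(t)
#'
#' `delta(t) = [ 2 sum_{i>j} (r_ij(t) - r_ij(0))^2 / (N(N-1)) ]^(1/2)`:
#' the DRMS of frame t against the initial frame, measuring how far the
#' internal-distance pattern has reorganised.
#'
#' @param traj a `chrom_trajectory`.
#' @param every compute at every `every`-th frame (>= 1).
#' @return data.frame with `t` (tau_BD) and `delta` (a); `delta[t = 0] = 0`.
#' @export
delta_of_t <- function(traj, every = 1L) {
  T <- n_frames(traj)
  idx <- unique(c(1L, seq.int(1L, T, by = as.integer(every)), T))
  d0 <- dist(frame_at(traj, 1))
  del <- vapply(idx, function(t) {
    if (t == 1) return(0)
    sqrt(mean((dist(frame_at(traj, t)) - d0)^2))
  }, numeric(1))
  data.frame(t = (idx - 1) * traj$frame_interval, delta = del)
}

#' Equilibrium structural deviation, exact finite sum
#'
#' `delta_eq^2 = 2 a^2 / (N(N-1)) * sum_{s=1}^{N-1} (N-s) s^(2 nu)`,
#' the long-time limit of delta(t) under the scaling ansatz
#' `R^2(s) = a^2 s^(2 nu)`, evaluated by exact summation (no continuum
#' approximation).
#'
#' @param N chain length (>= 2).
#' @param nu structure scaling exponent (1/3 space-filling, 1/2 ideal).
#' @param a bead diameter (default 1, reduced units).
#' @return delta_eq in units of a.
#' @export
delta_eq_analytic <- function(N, nu, a = 1) {
  stopifnot_scalar(N, "N")
  if (N < 2) stop("N must be >= 2")
  stopifnot_scalar(nu, "nu")
  s <- seq_len(N - 1)
  sqrt(2 * a^2 / (N * (N - 1)) * sum((N - s) * s^(2 * nu)))
}
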