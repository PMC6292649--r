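#' Physical unit system for the reduced model
#'
#' Reduced units are a = 1 (bead diameter), k_BT = 1, tau_BD = 1 (the
#' Brownian time of a single bead). The physical mapping uses a bead
#' diameter of 150 nm (one 50 kb locus), an effective nucleoplasmic
#' viscosity of 7 cP and T = 300 K, giving tau_BD of about 50 ms.
#'
#' @param a_nm bead diameter (nm).
#' @param eta_cP viscosity (centipoise).
#' @param T_K temperature (kelvin).
#' @return List of class `physical_units` including the derived
#'   `tau_BD_ms`.
#' @export
physical_units <- function(a_nm = 150, eta_cP = 7, T_K = 300) {
  stopifnot_scalar(a_nm, "a_nm", positive = TRUE)
  stopifnot_scalar(eta_cP, "eta_cP", positive = TRUE)
  stopifnot_scalar(T_K, "T_K", positive = TRUE)
  u <- structure(list(a_nm = a_nm, eta_cP = eta_cP, T_K = T_K),
                 class = "physical_units")
  u$tau_BD_ms <- brownian_time(u)
  u
}

#' @export
print.physical_units <- function(x, ...) {
  cat("<physical_units> a = ", x$a_nm, " nm, eta = ", x$eta_cP,
      " cP, T = ", x$T_K, " K, tau_BD = ", signif(x$tau_BD_ms, 3),
      " ms\n", sep = "")
  invisible(x)
}

#' Subdiffusion exponent from the structure exponent
#'
#' For a freely draining compact chain with `R(s) ~ s^nu` the loci-averaged
#' MSD grows as `t^beta` with `beta = 2 nu / (2 nu + 1)`: 0.4 for the
#' space-filling chain (nu = 1/3), 0.5 for the ideal chain (nu = 1/2).
#'
#' @param nu structure exponent in (0, 1].
#' @export
beta_from_nu <- function(nu) {
  if (any(nu <= 0 | nu > 1)) stop("nu must be in (0, 1]")
  2 * nu / (2 * nu + 1)
}

#' Relaxation-time exponent from the structure exponent
#'
#' A domain of s loci has size `xi ~ s^nu` and effective diffusivity
#' `D0 / s`, so its relaxation time scales as
#' `tau ~ xi^2 / D_eff ~ s^(2 nu + 1)`: 5/3 for nu = 1/3.
#'
#' @param nu structure exponent.
#' @export
tau_exponent_from_nu <- function(nu) 2 * nu + 1

#' Brownian time of a single bead
#'
#' `tau_BD = 3 pi eta a^3 / k_B T`, the time for a bead to diffuse over its
#' own diameter.
#'
#' @param units a [physical_units] object (the derived field is ignored).
#' @return tau_BD in milliseconds.
#' @export
brownian_time <- function(units = physical_units()) {
  kB <- 1.380649e-23 # J/K
  a <- units$a_nm * 1e-9
  eta <- units$eta_cP * 1e-3 # Pa s
  tau <- 3 * pi * eta * a^3 / (kB * units$T_K)
  tau * 1e3
}

#' Confining-sphere radius from the bead volume fraction
#'
#' With volume fraction `phi = N (a/2)^3 / R_s^3` (ratio of total bead
#' volume to sphere volume), `R_s = (a/2) (N / phi)^(1/3)`; N = 2712 at
#' phi = 0.1 gives R_s of about 15 a.
#'
#' @param N number of loci.
#' @param phi volume fraction in (0, 1).
#' @param a bead diameter.
#' @export
confinement_radius <- function(N, phi = 0.1, a = 1) {
  stopifnot_scalar(N, "N", positive = TRUE)
  if (phi <= 0 || phi > 1) stop("phi must be in (0, 1]")
  (a / 2) * (N / phi)^(1 / 3)
}

#' Reduced-to-physical conversions
#'
#' `to_physical_msd` converts an MSD in a^2 to micrometres squared;
#' `to_physical_time` converts a time in tau_BD to seconds. The `to_reduced_*`
#' functions are the exact inverses.
#'
#' @param msd_a2 MSD in units of a^2.
#' @param t_tauBD time in units of tau_BD.
#' @param msd_um2 MSD in micrometres squared.
#' @param t_s time in seconds.
#' @param units a [physical_units].
#' @export
to_physical_msd <- function(msd_a2, units = physical_units()) {
  msd_a2 * (units$a_nm * 1e-3)^2
}

#' @rdname to_physical_msd
#' @export
to_physical_time <- function(t_tauBD, units = physical_units()) {
  t_tauBD * units$tau_BD_ms * 1e-3
}

#' @rdname to_physical_msd
#' @export
to_reduced_msd <- function(msd_um2, units = physical_units()) {
  msd_um2 / (units$a_nm * 1e-3)^2
}

#' @rdname to_physical_msd
#' @export
to_reduced_time <- function(t_s, units = physical_units()) {
  t_s / (units$tau_BD_ms * 1e-3)
}

#' Print the unit table for a configuration
#'
#' @param units a [physical_units].
#' @param N chain length for the derived confinement radius.
#' @param phi volume fraction.
#' @export
unit_table <- function(units = physical_units(), N = 2712, phi = 0.1) {
  data.frame(
    quantity = c("bead diameter a", "viscosity eta", "temperature T",
                 "Brownian time tau_BD", "confinement radius R_s",
                 "MSD of 1 a^2", "time of 1e3 tau_BD"),
    value = c(units$a_nm, units$eta_cP, units$T_K,
              signif(units$tau_BD_ms, 4),
              signif(confinement_radius(N, phi), 4),
              signif(to_physical_msd(1, units), 4),
              signif(to_physical_time(1e3, units), 4)),
    unit = c("nm", "cP", "K", "ms", "a", "um^2", "s"))
}
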