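#' Default subcompartment type-pair contact energies
#'
#' Symmetric 6x6 matrix of contact energies (k_BT) in [chrom_types] order.
#' Entries are attractive (negative), strongest among B-type pairs and
#' weakest between A and B types, which qualitatively reproduces the
#' checkerboard contact pattern and the B-core / A-surface radial
#' organisation. Magnitudes are O(0.1-0.5 k_BT) and fully config-overridable;
#' they are deliberately generic rather than values trained on Hi-C.
#'
#' @return 6x6 numeric matrix with dimnames [chrom_types].
#' @export
default_type_matrix <- function() {
  m <- matrix(0, 6, 6, dimnames = list(chrom_types, chrom_types))
  diag(m) <- c(-0.50, -0.45, -0.35, -0.25, -0.30, -0.30)
  set <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  set("B3", "B2", -0.40); set("B3", "B1", -0.30); set("B2", "B1", -0.30)
  set("A1", "A2", -0.25)
  for (b in c("B3", "B2", "B1")) for (a in c("A1", "A2")) set(b, a, -0.10)
  for (t in c("B3", "B2", "B1", "A1", "A2")) set("NA", t, -0.15)
  m
}

#' Default genomic-distance condensation energies
#'
#' Tabulated attraction gamma(d) (k_BT) applied to the contact indicator of
#' pairs at genomic separation d, for 2 <= d <= d_max. The default family
#' gamma(d) = -(g1/d + g2/d^2) decays monotonically in magnitude with d,
#' condensing the chain most strongly at short genomic range.
#'
#' @param d_max cutoff separation (loci).
#' @param g1,g2 positive coefficients (k_BT).
#' @return Numeric vector `g` with `g[d]` = gamma(d); entries below d = 2 are 0.
#' @export
default_ideal_gamma <- function(d_max = 500L, g1 = 0.35, g2 = 3.7) {
  d <- seq_len(d_max)
  g <- -(g1 / d + g2 / d^2)
  g[1] <- 0 # defined for d >= 2
  g
}

#' Model parameters for the heteropolymer chromosome
#'
#' Collects every energy-term coefficient in reduced units (lengths in a,
#' energies in k_BT): harmonic bonds, short-range harmonic excluded volume,
#' type-pair contact energies, loop attractions, genomic-distance
#' condensation, and a one-sided harmonic spherical confinement whose radius
#' follows from the bead volume fraction phi unless overridden.
#'
#' @param n_loci chain length, used to derive `R_s` from `phi` when `R_s` is
#'   not given explicitly.
#' @param bond_k,bond_r0 harmonic bond stiffness (k_BT/a^2; E = k/2 (r-r0)^2)
#'   and rest length (a).
#' @param hardcore_sigma excluded-volume diameter (a).
#' @param ev_k excluded-volume stiffness (k_BT/a^2; E = k/2 (sigma-r)^2 for
#'   r < sigma, non-bonded pairs only).
#' @param mu contact-function steepness (1/a).
#' @param r_c contact-function midpoint (a).
#' @param type_matrix symmetric 6x6 contact-energy matrix (k_BT).
#' @param loop_eps loop attraction strength (k_BT; negative = attractive).
#' @param ideal_gamma condensation table, `ideal_gamma[d]` in k_BT.
#' @param d_max condensation cutoff separation (loci).
#' @param phi bead volume fraction used to derive `R_s`.
#' @param R_s confinement radius (a); `NULL` derives it from `n_loci`/`phi`.
#' @param wall_k confinement stiffness (k_BT/a^2; E = k (|r|-R_s)^2 outside).
#' @return An object of class `chrom_params`.
#' @export
chrom_params <- function(n_loci = NULL,
                         bond_k = 200, bond_r0 = 1,
                         hardcore_sigma = 1, ev_k = 300,
                         mu = 3, r_c = 1.5,
                         type_matrix = default_type_matrix(),
                         loop_eps = -2,
                         ideal_gamma = default_ideal_gamma(),
                         d_max = 500L,
                         phi = 0.1, R_s = NULL, wall_k = 100) {
  stopifnot_scalar(mu, "mu", positive = TRUE)
  stopifnot_scalar(r_c, "r_c", positive = TRUE)
  if (!is.matrix(type_matrix) || any(dim(type_matrix) != c(6, 6)))
    stop("type_matrix must be 6x6")
  if (max(abs(type_matrix - t(type_matrix))) > 1e-12)
    stop("type_matrix must be symmetric")
  if (is.null(R_s)) {
    if (is.null(n_loci))
      stop("either n_loci (to derive R_s from phi) or R_s must be given")
    R_s <- confinement_radius(n_loci, phi)
  }
  stopifnot_scalar(R_s, "R_s", positive = TRUE)
  d_max <- as.integer(min(d_max, length(ideal_gamma)))
  structure(list(bond_k = bond_k, bond_r0 = bond_r0,
                 hardcore_sigma = hardcore_sigma, ev_k = ev_k,
                 mu = mu, r_c = r_c,
                 type_matrix = type_matrix, loop_eps = loop_eps,
                 ideal_gamma = ideal_gamma, d_max = d_max,
                 phi = phi, R_s = R_s, wall_k = wall_k),
            class = "chrom_params")
}

#' @export
print.chrom_params <- function(x, ...) {
  cat("<chrom_params> mu=", x$mu, " r_c=", x$r_c,
      " bond(k=", x$bond_k, ", r0=", x$bond_r0, ")",
      " ev(sigma=", x$hardcore_sigma, ", k=", x$ev_k, ")\n",
      "  loop_eps=", x$loop_eps, " d_max=", x$d_max,
      " R_s=", signif(x$R_s, 4), " wall_k=", x$wall_k, "\n", sep = "")
  invisible(x)
}

#' Smooth contact indicator
#'
#' f(r) = (1 + tanh(mu (r_c - r))) / 2: a smooth, monotonically nonincreasing
#' sigmoid with f(r_c) = 1/2, f(0) -> 1 and f(Inf) -> 0. Ensemble averages
#' of f define the model contact probability c_ij = <f(r_ij)>.
#'
#' @param r distance(s), >= 0 (a).
#' @param mu steepness (1/a).
#' @param r_c midpoint (a).
#' @return Values in (0, 1), vectorised over `r`.
#' @export
contact_indicator <- function(r, mu = 3, r_c = 1.5) {
  if (any(r < 0)) stop("r must be nonnegative")
  0.5 * (1 + tanh(mu * (r_c - r)))
}

# internal: marshal params + annotation for the C++ kernels
cpp_args <- function(conf, annotation, params, confine = TRUE) {
  if (!is.matrix(conf) || ncol(conf) != 3L)
    stop("conformation must be an N x 3 matrix")
  if (nrow(conf) != annotation$n_loci)
    stop("conformation has ", nrow(conf), " beads but annotation has ",
         annotation$n_loci, " loci")
  gam <- c(0, params$ideal_gamma) # shift so gam[d + 1] = gamma(d)
  list(coords = conf,
       labels = label_codes(annotation$labels),
       type_matrix = params$type_matrix,
       loop_i = as.integer(annotation$loops[, 1L]),
       loop_j = as.integer(annotation$loops[, 2L]),
       loop_eps = params$loop_eps,
       gamma_tab = gam,
       d_max = as.integer(params$d_max),
       mu = params$mu, rc = params$r_c,
       sigma = params$hardcore_sigma, ev_k = params$ev_k,
       bond_k = params$bond_k, bond_r0 = params$bond_r0,
       Rs = params$R_s,
       wall_k = if (confine) params$wall_k else -1)
}

#' Decomposed potential energy of a conformation
#'
#' Evaluates the six energy classes separately (all in k_BT):
#' bonded springs, non-bonded excluded volume, type-pair contacts
#' `sum_{i<j} E(T_i,T_j) f(r_ij)`, loop attractions
#' `loop_eps sum_{(i,j) in loops} f(r_ij)`, genomic-distance condensation
#' `sum_{|i-j| <= d_max} gamma(|i-j|) f(r_ij)`, and the one-sided spherical
#' confinement `wall_k sum_i max(0, |r_i| - R_s)^2`.
#'
#' @param conf N x 3 coordinate matrix (a).
#' @param annotation a [chrom_annotation] with N loci.
#' @param params a [chrom_params].
#' @param confine include the confinement term (set `FALSE` to evaluate the
#'   translation-invariant internal energy only).
#' @return A list of class `energy_report` with the per-term totals and
#'   `total`, their sum.
#' @export
energy_decomposed <- function(conf, annotation, params, confine = TRUE) {
  a <- cpp_args(conf, annotation, params, confine)
  e <- do.call(cpp_energy_terms, a)
  out <- as.list(e)
  out$total <- sum(e)
  class(out) <- "energy_report"
  out
}

#' @export
print.energy_report <- function(x, ...) {
  terms <- unlist(x[setdiff(names(x), "total")])
  cat("<energy_report> (k_BT)\n")
  for (nm in names(terms)) cat(sprintf("  %-12s %12.6g\n", nm, terms[[nm]]))
  cat(sprintf("  %-12s %12.6g\n", "total", x$total))
  invisible(x)
}

#' Total force on every bead
#'
#' Minus the gradient of the total energy of [energy_decomposed()], evaluated
#' analytically (k_BT/a).
#'
#' @inheritParams energy_decomposed
#' @return N x 3 matrix of forces.
#' @export
total_force <- function(conf, annotation, params, confine = TRUE) {
  a <- cpp_args(conf, annotation, params, confine)
  a$coords0 <- NULL
  do.call(cpp_total_force, a)
}

#' Write / read model parameters as a structured config file
#'
#' JSON with the 6x6 type matrix carried with explicit row/column labels.
#'
#' @param params a [chrom_params].
#' @param path file path.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x$type_matrix <- list(types = chrom_types,
                        energies = unname(as.matrix(params$type_matrix)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- matrix(unlist(x$type_matrix$energies), 6, 6,
               dimnames = list(x$type_matrix$types, x$type_matrix$types))
  chrom_params(bond_k = x$bond_k, bond_r0 = x$bond_r0,
               hardcore_sigma = x$hardcore_sigma, ev_k = x$ev_k,
               mu = x$mu, r_c = x$r_c, type_matrix = tm,
               loop_eps = x$loop_eps, ideal_gamma = x$ideal_gamma,
               d_max = x$d_max, phi = x$phi, R_s = x$R_s, wall_k = x$wall_k)
}
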