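# pair-type masks for the A/B decomposition: A = {A1, A2}, B = {B1, B2, B3};
# "NA"-type loci belong to neither class and enter only the unfiltered curve
pair_filter_mask <- function(labels, type_filter) {
  if (type_filter == "all") return(NULL)
  isA <- labels %in% c("A1", "A2")
  isB <- labels %in% c("B1", "B2", "B3")
  switch(type_filter,
         AA = outer(isA, isA, "&"),
         BB = outer(isB, isB, "&"),
         AB = outer(isA, isB, "&") | outer(isB, isA, "&"),
         stop("type_filter must be one of all, AA, BB, AB"))
}

#' Spatial correlation of loci displacements (displacement correlation
#' spectroscopy)
#'
#' For each time origin, loci pairs are binned by their instantaneous
#' separation r, and the dot product of their displacement vectors over the
#' interval `dt_lag` is accumulated per bin:
#' `C(r) = < sum_pairs dr_i . dr_j delta(r_ij - r) / sum_pairs delta(r_ij - r) >_t`.
#'
#' @param traj a `chrom_trajectory`.
#' @param dt_lag displacement interval Delta t (multiple of the frame
#'   interval).
#' @param bins distance-bin edges (a); default 0.5 a bins up to `r_max`.
#' @param r_max upper distance bound for the default bins.
#' @param type_filter `"all"`, `"AA"`, `"BB"` or `"AB"` pair restriction
#'   (requires `annotation`).
#' @param annotation a [chrom_annotation] (for type filters).
#' @param slab optional length-2 z-interval: both loci must lie in the slab
#'   at the time origin (equatorial-slab analysis).
#' @param t0_stride subsample time origins by this stride (cost control).
#' @return data.frame of class `spatial_correlation` with `r_lo`, `r_hi`,
#'   `r_mid`, `value` (a^2; NA where a bin received no pairs) and `n_pairs`.
#' @export
displacement_correlation <- function(traj, dt_lag, bins = NULL, r_max = NULL,
                                     type_filter = "all", annotation = NULL,
                                     slab = NULL, t0_stride = 1L) {
  Lf <- lag_frames(traj, dt_lag)
  if (Lf < 1) stop("dt_lag must be at least one frame interval")
  T <- n_frames(traj)
  if (is.null(bins)) {
    if (is.null(r_max)) r_max <- 2 * max(abs(traj$frames))
    bins <- seq(0, r_max, by = 0.5)
  }
  nb <- length(bins) - 1
  mask <- if (type_filter != "all") {
    if (is.null(annotation)) stop("type filters need an annotation")
    m <- pair_filter_mask(annotation$labels, type_filter)
    m[upper.tri(m)]
  } else NULL
  acc <- num <- rep(0, nb)
  t0s <- seq.int(1L, T - Lf, by = as.integer(t0_stride))
  for (t0 in t0s) {
    x0 <- frame_at(traj, t0)
    x1 <- frame_at(traj, t0 + Lf)
    dvec <- x1 - x0
    dots <- tcrossprod(dvec)[upper.tri(diag(nrow(x0)))]
    rr <- as.vector(dist(x0))
    keep <- rep(TRUE, length(rr))
    if (!is.null(mask)) keep <- keep & mask
    if (!is.null(slab)) {
      inslab <- x0[, 3] >= slab[1] & x0[, 3] <= slab[2]
      pm <- outer(inslab, inslab, "&")[upper.tri(diag(nrow(x0)))]
      keep <- keep & pm
    }
    bi <- findInterval(rr, bins, rightmost.closed = TRUE)
    ok <- keep & bi >= 1 & bi <= nb
    if (!any(ok)) next
    acc <- acc + vapply(seq_len(nb), function(b)
      sum(dots[ok & bi == b]), numeric(1))
    num <- num + tabulate(bi[ok], nbins = nb)
  }
  val <- ifelse(num > 0, acc / num, NA_real_)
  out <- data.frame(r_lo = bins[-length(bins)], r_hi = bins[-1],
                    r_mid = (bins[-1] + bins[-length(bins)]) / 2,
                    value = val, n_pairs = num)
  attr(out, "dt_lag") <- dt_lag
  attr(out, "type_filter") <- type_filter
  class(out) <- c("spatial_correlation", "data.frame")
  out
}

#' Correlation length of a displacement-correlation profile
#'
#' `l_c = integral_0^inf C(r) / C(a) dr`, evaluated by the trapezoidal rule
#' on the binned profile, truncated at the first bin where the normalised
#' value drops below `cut` (or at the last finite bin). The profile is
#' extended to r = 0 with the value of the first finite bin.
#'
#' @param C a `spatial_correlation` (or data.frame with `r_mid`, `value`).
#' @param a normalisation distance (C is normalised by its value at r = a).
#' @param cut truncation threshold on the normalised profile.
#' @return l_c (a).
#' @export
correlation_length <- function(C, a = 1, cut = 0.01) {
  r <- C$r_mid
  v <- C$value
  # value at r = a, interpolated between bin midpoints (falls back to the
  # containing bin at the profile edge)
  finite <- is.finite(v)
  Ca <- if (sum(finite) >= 2 && a >= min(r[finite]) && a <= max(r[finite])) {
    stats::approx(r[finite], v[finite], xout = a)$y
  } else {
    ia <- which(C$r_lo <= a & C$r_hi > a)
    if (length(ia) == 1) v[ia] else NA_real_
  }
  if (!is.finite(Ca) || Ca <= 0)
    stop("C(a) is not positive; correlation length undefined")
  vn <- v / Ca
  fin <- which(is.finite(vn))
  if (length(fin) < 2) stop("too few finite bins")
  lastf <- max(fin)
  below <- which(vn < cut & is.finite(vn))
  stop_at <- if (length(below) > 0) min(below) else lastf
  keep <- fin[fin <= stop_at]
  rr <- c(0, r[keep])
  vv <- c(vn[keep][1], vn[keep])
  sum(diff(rr) * (head(vv, -1) + tail(vv, -1)) / 2)
}

#' Coarse-grained velocity correlation of loci
#'
#' The coarse velocity over interval Delta t is
#' `v(t) = [r(t + Dt) - r(t)] / Dt`; the function returns
#' `C(t) = < v_i(t0) . v_j(t0 + t) >_t0` for the locus pair (i, j) (i = j
#' gives the mean velocity autocorrelation), plus the form normalised by
#' C(0).
#'
#' @param traj a `chrom_trajectory`.
#' @param dt_lag velocity coarse-graining interval Delta t.
#' @param pair length-1 (autocorrelation) or length-2 locus indices.
#' @param t_lags correlation lags (default multiples of the frame interval
#'   up to half the trajectory).
#' @return data.frame with `t`, `value` and `normalized`.
#' @export
velocity_correlation <- function(traj, dt_lag, pair,
                                 t_lags = NULL) {
  Lf <- lag_frames(traj, dt_lag)
  if (Lf < 1) stop("dt_lag must be at least one frame interval")
  T <- n_frames(traj)
  if (length(pair) == 1) pair <- c(pair, pair)
  nv <- T - Lf # number of velocity samples
  vi <- (traj$frames[seq.int(1 + Lf, T), pair[1], ] -
           traj$frames[seq_len(nv), pair[1], ]) / dt_lag
  vj <- (traj$frames[seq.int(1 + Lf, T), pair[2], ] -
           traj$frames[seq_len(nv), pair[2], ]) / dt_lag
  if (is.null(t_lags)) {
    t_lags <- unique(round(10^seq(0, log10(nv - 1), by = 0.1)))
    t_lags <- c(0, t_lags[t_lags < nv]) * traj$frame_interval
  }
  Lt <- round(t_lags / traj$frame_interval)
  val <- vapply(Lt, function(l) {
    n <- nv - l
    if (n < 1) return(NA_real_)
    mean(rowSums(vi[seq_len(n), , drop = FALSE] *
                   vj[seq.int(1 + l, l + n), , drop = FALSE]))
  }, numeric(1))
  c0 <- val[Lt == 0]
  if (length(c0) == 0) c0 <- NA_real_
  data.frame(t = t_lags, value = val, normalized = val / c0)
}

#' Fractional-Langevin-motion velocity correlation, closed form
#'
#' `C(x) = (|x - 1|^beta + |x + 1|^beta - 2 |x|^beta) / 2` with
#' `x = t / Delta t`: the normalised coarse velocity autocorrelation of
#' fractional Langevin motion with MSD exponent beta.
#'
#' @param x rescaled lag t / Delta t (vectorised).
#' @param beta MSD exponent in (0, 2).
#' @export
flm_velocity_model <- function(x, beta) {
  (abs(x - 1)^beta + abs(x + 1)^beta - 2 * abs(x)^beta) / 2
}

#' Rouse-mode amplitudes
#'
#' Open-chain cosine transform
#' `X_p(t) = (1/N) sum_n r_n(t) cos(p pi (n - 1/2) / N)`; the amplitude is
#' the time (or ensemble) mean of `|X_p|^2`. For an equilibrium ideal chain
#' `<X_p^2> ~ p^-2` (exactly `propto 1 / sin^2(p pi / 2N)`); for a
#' space-filling chain the large-p slope is -(1 + 2 nu) = -5/3.
#'
#' @param traj a `chrom_trajectory` or a list of conformations.
#' @param p_list mode indices (>= 1).
#' @return data.frame of class `rouse_spectrum` with `p` and `amplitude`
#'   (a^2).
#' @export
rouse_mode_amplitudes <- function(traj, p_list = NULL) {
  ens <- if (inherits(traj, "chrom_trajectory")) {
    lapply(seq_len(n_frames(traj)), function(t) frame_at(traj, t))
  } else traj
  N <- nrow(ens[[1]])
  if (is.null(p_list)) p_list <- seq_len(N - 1)
  p_list <- as.integer(p_list)
  if (any(p_list < 1)) stop("mode indices must be >= 1")
  n <- seq_len(N)
  # N x P cosine basis
  B <- vapply(p_list, function(p) cos(p * pi * (n - 0.5) / N), numeric(N))
  amp <- Reduce(`+`, lapply(ens, function(cf) {
    X <- crossprod(B, cf) / N # P x 3
    rowSums(X^2)
  })) / length(ens)
  out <- data.frame(p = p_list, amplitude = amp)
  class(out) <- c("rouse_spectrum", "data.frame")
  out
}

# deterministic unit vectors on the sphere (seeded, independent of R's RNG)
unit_directions <- function(n, seed) {
  with_seed(seed, {
    m <- matrix(rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
}

#' Intermediate scattering function
#'
#' `F_k(t) = < (1/N) sum_m e^{i k.r_m(t + t0)} sum_n e^{-i k.r_n(t0)} >`,
#' averaged over time origins and `n_directions` random directions of the
#' wave vector (real part reported). F_k(t) probes density relaxation on the
#' length scale 2 pi / k.
#'
#' @param traj a `chrom_trajectory`.
#' @param k wave number (1/a).
#' @param n_directions number of random unit vectors (default 32).
#' @param lags correlation lags (default [log_lags()] plus 0).
#' @param seed seed for the direction sample.
#' @return data.frame of class `scattering_curve` with `t` and `value`;
#'   attribute `k`.
#' @export
intermediate_scattering <- function(traj, k, n_directions = 32L,
                                    lags = NULL, seed = 1L) {
  stopifnot_scalar(k, "k")
  if (k < 0) stop("k must be nonnegative")
  T <- n_frames(traj)
  N <- n_loci(traj)
  if (is.null(lags)) lags <- c(0, log_lags(traj))
  lags <- sort(unique(lags))
  Lf <- lag_frames(traj, lags)
  dirs <- unit_directions(n_directions, seed)
  acc <- rep(0, length(Lf))
  cnt <- rep(0, length(Lf))
  flat <- matrix(traj$frames, nrow = T * N, ncol = 3) # (t,i) major over t
  for (d in seq_len(nrow(dirs))) {
    proj <- matrix(flat %*% dirs[d, ], nrow = T, ncol = N)
    A <- rowSums(exp(1i * k * proj)) # length T
    for (li in seq_along(Lf)) {
      l <- Lf[li]
      n <- T - l
      v <- Re(A[seq.int(1 + l, T)] * Conj(A[seq_len(n)])) / N
      acc[li] <- acc[li] + sum(v)
      cnt[li] <- cnt[li] + n
    }
  }
  out <- data.frame(t = lags, value = acc / cnt)
  attr(out, "k") <- k
  attr(out, "n_directions") <- n_directions
  class(out) <- c("scattering_curve", "data.frame")
  out
}

#' Relaxation time from a scattering curve
#'
#' `tau_k = integral_0^inf F_k(t) / F_k(0) dt`, evaluated by the trapezoidal
#' rule over the measured lags with an exponential-tail extension fitted on
#' the last decade of lags (the infinite upper limit is not computable from
#' finite data).
#'
#' @param F a `scattering_curve`.
#' @return tau_k (tau_BD).
#' @export
relaxation_time <- function(F) {
  t <- F$t
  v <- F$value
  if (t[1] != 0) stop("scattering curve must include lag 0")
  f0 <- v[1]
  if (!is.finite(f0) || f0 <= 0) stop("F(0) must be positive")
  vn <- v / f0
  # truncate at first nonpositive value (noise floor)
  neg <- which(vn <= 0)
  last <- if (length(neg) > 0) neg[1] - 1 else length(vn)
  if (last < 2) return(0)
  tt <- t[seq_len(last)]
  vv <- vn[seq_len(last)]
  integral <- sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
  # exponential tail fitted on the last decade of lags
  tl <- tt[tt >= max(tt) / 10 & tt > 0]
  vl <- vv[tt >= max(tt) / 10 & tt > 0]
  ok <- vl > 0
  tail_part <- 0
  if (sum(ok) >= 3) {
    fit <- lm(log(vl[ok]) ~ tl[ok])
    rate <- -coef(fit)[2]
    if (is.finite(rate) && rate > 0)
      tail_part <- vv[last] / rate
  }
  unname(integral + tail_part)
}

#' Map a wave number to a genomic segment size
#'
#' The volume probed at wave number k has linear size `xi = 2 pi / k`; with
#' `xi ~ a s^nu` this corresponds to `s = (2 pi / (k a))^(1/nu)` loci.
#'
#' @param k wave number (1/a).
#' @param a bead diameter.
#' @param nu structure exponent.
#' @export
k_to_genomic_size <- function(k, a = 1, nu = 1 / 3) {
  (2 * pi / (k * a))^(1 / nu)
}
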