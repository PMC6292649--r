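test_that("displacement correlations match hand arithmetic and limiting cases", {
  # rigid translation by d between frames: C = |d|^2 in every occupied bin
  base <- random_conformation(6, sd = 3)
  d <- c(0.4, -0.1, 0.2)
  fr <- array(0, c(2, 6, 3))
  fr[1, , ] <- base
  fr[2, , ] <- sweep(base, 2, -d)
  tr <- manual_trajectory(fr)
  C <- displacement_correlation(tr, 1, bins = seq(0, 20, 1))
  occ <- C$n_pairs > 0
  expect_true(all(abs(C$value[occ] - sum(d^2)) < 1e-12))
  expect_true(all(is.na(C$value[!occ])))
  # independent isotropic displacements: zero within 3 SE
  set.seed(18)
  T <- 400
  frn <- array(0, c(T, 30, 3))
  frn[1, , ] <- random_conformation(30, sd = 4)
  steps <- array(rnorm((T - 1) * 30 * 3, sd = 0.5), c(T - 1, 30, 3))
  for (t in 2:T) frn[t, , ] <- frn[1, , ] + steps[t - 1, , ]
  trn <- manual_trajectory(frn)
  Cn <- displacement_correlation(trn, 1, bins = c(0, 4, 8, 16))
  se <- 2 * 0.5^2 * sqrt(3) / sqrt(Cn$n_pairs) # per-bin SE scale
  expect_true(all(abs(Cn$value) < 3 * se + 1e-9, na.rm = TRUE))
  # 3-bead 2-frame toy against explicit dot products
  x0 <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 3.1, 0))
  x1 <- rbind(c(0.1, 0, 0), c(1.2, 0.2, 0), c(-0.1, 3.0, 0.3))
  fr3 <- array(0, c(2, 3, 3))
  fr3[1, , ] <- x0
  fr3[2, , ] <- x1
  tr3 <- manual_trajectory(fr3)
  C3 <- displacement_correlation(tr3, 1, bins = c(0, 2, 3, 4))
  d1 <- x1[1, ] - x0[1, ]; d2 <- x1[2, ] - x0[2, ]; d3 <- x1[3, ] - x0[3, ]
  # pair (1,2): r = 1.2 -> bin 1; pairs (1,3) r = 3.1 and (2,3) r = 3.33 -> bin 3
  expect_equal(C3$value[1], sum(d1 * d2), tolerance = 1e-12)
  expect_equal(C3$value[3],
               mean(c(sum(d1 * d3), sum(d2 * d3))), tolerance = 1e-12)
  expect_true(is.na(C3$value[2]))
})

test_that("type-decomposed correlations recombine to the unfiltered curve", {
  set.seed(19)
  N <- 12
  ann <- chrom_annotation(rep(c("A1", "B3", "A2", "B1"), 3))
  T <- 6
  fr <- array(rnorm(T * N * 3, sd = 2), c(T, N, 3))
  tr <- manual_trajectory(fr)
  bins <- seq(0, 12, 2)
  Call <- displacement_correlation(tr, 1, bins = bins)
  parts <- lapply(c("AA", "BB", "AB"), function(fl)
    displacement_correlation(tr, 1, bins = bins, type_filter = fl,
                             annotation = ann))
  num <- Reduce(`+`, lapply(parts, function(p)
    ifelse(p$n_pairs > 0, p$value * p$n_pairs, 0)))
  den <- Reduce(`+`, lapply(parts, function(p) p$n_pairs))
  expect_equal(den, Call$n_pairs)
  expect_equal(num / den, Call$value, tolerance = 1e-12)
})

test_that("correlation length reproduces closed forms and scale invariance", {
  r_mid <- seq(0.025, 20, by = 0.05)
  prof <- data.frame(r_lo = r_mid - 0.025, r_hi = r_mid + 0.025,
                     r_mid = r_mid, value = 5 * exp(-r_mid), n_pairs = 1000)
  expect_equal(correlation_length(prof), exp(1), tolerance = 0.02)
  # constant over [0, L] then zero
  prof2 <- prof
  prof2$value <- ifelse(prof2$r_mid <= 6, 2, 0)
  expect_equal(correlation_length(prof2), 6, tolerance = 0.1)
  # normalisation invariance
  prof3 <- prof
  prof3$value <- prof$value * 17
  expect_equal(correlation_length(prof3), correlation_length(prof))
  prof4 <- prof
  prof4$value <- -prof4$value
  expect_error(correlation_length(prof4), "not positive")
})

test_that("velocity correlations have the fLm closed-form limits", {
  expect_equal(flm_velocity_model(0, 0.37), 1)
  expect_equal(flm_velocity_model(c(1, 2, 5), 1), c(0, 0, 0))
  expect_equal(flm_velocity_model(1, 0.5), (sqrt(2) - 2) / 2, tolerance = 1e-12)
  # ballistic trajectory: normalised correlation 1 at all lags
  v <- c(0.2, 0.1, -0.05)
  T <- 60
  fr <- array(0, c(T, 2, 3))
  for (t in seq_len(T)) fr[t, , ] <- rbind(v * t, c(1, 1, 1) + v * t)
  tr <- manual_trajectory(fr)
  vc <- velocity_correlation(tr, 5, pair = 1, t_lags = c(0, 5, 10))
  expect_equal(vc$normalized, rep(1, 3), tolerance = 1e-10)
  # Rouse interior-locus anticorrelation dip near t = Delta t: the fLm
  # closed form at beta = 1/2 gives -0.293 there
  trr <- rouse_reference_traj()
  dip <- mean(vapply(seq(64, 192, by = 16), function(i)
    velocity_correlation(trr, 150, pair = i,
                         t_lags = c(0, 150))$normalized[2], numeric(1)))
  expect_gt(dip, -0.35)
  expect_lt(dip, -0.25)
})

test_that("Rouse-mode amplitudes match ideal-chain scaling", {
  # rigid chain: amplitudes constant over time
  base <- random_conformation(8)
  fr <- array(0, c(5, 8, 3))
  for (t in 1:5) fr[t, , ] <- base
  rs0 <- rouse_mode_amplitudes(manual_trajectory(fr), p_list = 1:4)
  rs1 <- rouse_mode_amplitudes(list(base), p_list = 1:4)
  expect_equal(rs0$amplitude, rs1$amplitude, tolerance = 1e-12)
  # equilibrium Gaussian ensemble: log-log slope -2 over p in [2, N/8]
  ens <- make_rouse_ensemble(128, 1, 3000, seed = 20)
  rs <- rouse_mode_amplitudes(ens, p_list = 2:16)
  slope <- fit_power_law(rs$p, rs$amplitude, c(2, 16))$exponent
  expect_lt(abs(slope + 2), 0.1)
})

test_that("intermediate scattering has exact limits and free-bead decay", {
  set.seed(21)
  fr <- array(rnorm(10 * 6 * 3, sd = 2), c(10, 6, 3))
  tr <- manual_trajectory(fr)
  # k -> 0: F = N for all lags
  F0 <- intermediate_scattering(tr, 1e-9, n_directions = 4, lags = c(0, 1, 5))
  expect_equal(F0$value, rep(6, 3), tolerance = 1e-6)
  # frozen conformation: F(t) = F(0) exactly
  frz <- array(0, c(8, 6, 3))
  for (t in 1:8) frz[t, , ] <- fr[1, , ]
  Fz <- intermediate_scattering(manual_trajectory(frz), 2, lags = c(0, 2, 5))
  expect_equal(Fz$value, rep(Fz$value[1], 3), tolerance = 1e-10)
  # free Brownian bead: F_k(t)/F_k(0) = exp(-k^2 t)
  reps <- sapply(1:40, function(s) {
    trb <- brownian_run(matrix(0, 1, 3), uniform_annotation(1), free_params(),
                        t_total = 60, dt = 0.01, frame_interval = 0.5,
                        seed = 400 + s, cap_reject = 1e9)
    intermediate_scattering(trb, 1, n_directions = 8,
                            lags = c(0, 0.5, 1, 2), seed = s)$value
  })
  got <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  want <- exp(-c(0, 0.5, 1, 2))
  expect_true(all(abs(got - want) < 3 * se + 0.01))
})

test_that("relaxation times integrate normalised decay curves", {
  t <- c(0, 10^seq(-1, 2.3, 0.05))
  Fc <- data.frame(t = t, value = 4 * exp(-t / 3))
  class(Fc) <- c("scattering_curve", "data.frame")
  expect_equal(relaxation_time(Fc), 3, tolerance = 0.01)
  expect_equal(k_to_genomic_size(2 * pi, 1, 0.41), 1)
  expect_equal(k_to_genomic_size(pi, 1, 1 / 3), 8, tolerance = 1e-12)
})

test_that("relaxation slows at smaller wave numbers on a collapsed passive run", {
  st <- collapsed_state()
  ks <- 2 * pi / c(1.5, 3, 6)
  tk <- vapply(ks, function(k)
    relaxation_time(intermediate_scattering(st$traj, k, n_directions = 24,
                                            seed = 3)), numeric(1))
  # tau_k nonincreasing in k == nondecreasing with length scale
  expect_true(all(diff(tk) > 0))
})
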