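test_that("time-averaged MSD matches closed forms and a brute-force oracle", {
  # static trajectory: all zeros
  fr <- array(0, c(50, 3, 3))
  tr <- manual_trajectory(fr)
  expect_equal(msd_locus(tr, 1, lags = c(1, 5, 10))$value, rep(0, 3))
  # ballistic motion: MSD = |v|^2 t^2 exactly
  v <- c(0.3, -0.2, 0.1)
  T <- 40
  frb <- array(0, c(T, 2, 3))
  for (t in seq_len(T)) frb[t, , ] <- rbind(v * (t - 1), c(0, 0, 0))
  trb <- manual_trajectory(frb)
  lags <- c(1, 2, 7)
  expect_equal(msd_locus(trb, 1, lags = lags)$value,
               sum(v^2) * lags^2, tolerance = 1e-12)
  # brute-force oracle over all (t0, t0 + t) pairs on a random 200-frame toy
  set.seed(14)
  frr <- array(rnorm(200 * 4 * 3), c(200, 4, 3))
  trr <- manual_trajectory(frr)
  for (i in c(1, 3)) for (L in c(1, 17, 100)) {
    hand <- mean(vapply(seq_len(200 - L), function(t0)
      sum((frr[t0 + L, i, ] - frr[t0, i, ])^2), numeric(1)))
    expect_equal(msd_locus(trr, i, lags = L)$value, hand, tolerance = 1e-12)
  }
  expect_error(msd_locus(trr, 9, lags = 1), "out of range")
})

test_that("aggregate MSD scopes behave consistently", {
  set.seed(15)
  frr <- array(rnorm(100 * 5 * 3), c(100, 5, 3))
  trr <- manual_trajectory(frr)
  lags <- c(1, 5, 20)
  # single-locus selection equals msd_locus
  expect_equal(msd_aggregate(trr, 3, lags = lags)$value,
               msd_locus(trr, 3, lags = lags)$value)
  # label-subset mean equals hand average of member curves
  ann <- chrom_annotation(c("A1", "B3", "A1", "NA", "A2"))
  sub <- msd_aggregate(trr, c("A1", "A2"), lags = lags, annotation = ann)
  hand <- (msd_locus(trr, 1, lags = lags)$value +
             msd_locus(trr, 3, lags = lags)$value +
             msd_locus(trr, 5, lags = lags)$value) / 3
  expect_equal(sub$value, hand, tolerance = 1e-12)
  # "all" equals the mean over loci
  all5 <- msd_aggregate(trr, "all", lags = lags)$value
  hand5 <- rowMeans(vapply(1:5, function(i)
    msd_locus(trr, i, lags = lags)$value, numeric(3)))
  expect_equal(all5, hand5, tolerance = 1e-12)
  # com of a rigidly translating chain is ballistic
  v <- c(0.1, 0.2, -0.3)
  T <- 30
  base <- random_conformation(4)
  frt <- array(0, c(T, 4, 3))
  for (t in seq_len(T)) frt[t, , ] <- sweep(base, 2, -v * (t - 1))
  trt <- manual_trajectory(frt)
  expect_equal(msd_aggregate(trt, "com", lags = c(1, 4))$value,
               sum(v^2) * c(1, 16), tolerance = 1e-12)
})

test_that("diffusion exponent fits recover exact and simulated scaling", {
  lag <- 10^seq(0, 2, 0.1)
  curve <- data.frame(lag = lag, value = 2 * lag^0.4)
  f <- fit_diffusion_exponent(curve, c(1, 100))
  expect_equal(f$beta, 0.4, tolerance = 1e-12)
  expect_equal(f$C, 2, tolerance = 1e-10)
  expect_error(fit_diffusion_exponent(curve, c(98, 100)), "3 points")
  # free Brownian bead: slope of MSD vs 6 t within 5%
  tr <- brownian_run(matrix(0, 1, 3), uniform_annotation(1), free_params(),
                     t_total = 400, dt = 0.01, frame_interval = 0.5, seed = 16,
                     cap_reject = 1e9)
  msd <- msd_locus(tr, 1, lags = c(1, 2, 4, 8, 16))
  fb <- fit_diffusion_exponent(msd, c(1, 16))
  expect_equal(fb$beta, 1, tolerance = 0.05)
  expect_equal(fb$C, 6, tolerance = 0.3)
})

test_that("Rouse-chain loci-averaged MSD shows the t^(1/2) regime", {
  tr <- rouse_reference_traj()
  msd <- msd_aggregate(tr, "all")
  beta <- fit_diffusion_exponent(msd, c(2, 100))$beta
  expect_lt(abs(beta - 0.5), 0.05)
})

test_that("offset-power fits recover parameters and flag degeneracy", {
  lag <- seq(1, 100, by = 1)
  curve <- data.frame(lag = lag, value = 0.003 + 0.002 * lag^0.5)
  f <- fit_offset_power(curve)
  expect_equal(f$A, 0.003, tolerance = 1e-6)
  expect_equal(f$B, 0.002, tolerance = 1e-6)
  expect_equal(f$beta, 0.5, tolerance = 1e-6)
  # constant data: exponent unidentifiable
  f0 <- fit_offset_power(data.frame(lag = lag, value = rep(0.01, 100)))
  expect_false(f0$identifiable)
  expect_true(is.na(f0$beta))
  # noisy recovery across replicates
  set.seed(17)
  betas <- replicate(100, {
    y <- (0.003 + 0.002 * lag^0.5) * (1 + rnorm(100, sd = 0.05))
    fit_offset_power(data.frame(lag = lag, value = y))$beta
  })
  expect_lt(abs(mean(betas) - 0.5), 0.05)
})

test_that("structural deviation delta(t) is the DRMS from the initial frame", {
  # rigid translation: zero at all times
  base <- random_conformation(5)
  T <- 10
  fr <- array(0, c(T, 5, 3))
  for (t in seq_len(T)) fr[t, , ] <- sweep(base, 2, -c(t, 0, 0))
  tr <- manual_trajectory(fr)
  d <- delta_of_t(tr)
  expect_equal(d$delta[1], 0)
  expect_equal(max(abs(d$delta)), 0, tolerance = 1e-12)
  # hand value: 3 collinear beads 0,1,2 -> 0,1,3
  fr2 <- array(0, c(2, 3, 3))
  fr2[1, , ] <- cbind(0, 0, c(0, 1, 2))
  fr2[2, , ] <- cbind(0, 0, c(0, 1, 3))
  d2 <- delta_of_t(manual_trajectory(fr2))
  expect_equal(d2$delta[2], sqrt(2 / 3), tolerance = 1e-12)
})

test_that("the equilibrium deviation sum matches hand evaluation and the full-scale value", {
  # N = 2: single pair, delta_eq = a
  expect_equal(delta_eq_analytic(2, 0.37), 1)
  expect_equal(delta_eq_analytic(2, 0.5, a = 2.5), 2.5)
  # N = 3, nu = 1/2: hand summation (N-s) s over s = 1, 2
  expect_equal(delta_eq_analytic(3, 0.5), sqrt(4 / 3), tolerance = 1e-12)
  # chromosome-scale value, exact summation
  expect_equal(round(delta_eq_analytic(2712, 1 / 3), 1), 9.4)
  expect_error(delta_eq_analytic(1, 0.5), "N must be")
})

test_that("delta(t) on a collapsed run stays below the analytic equilibrium bound", {
  st <- collapsed_state()
  d <- delta_of_t(st$traj, every = 40)
  rc <- ree_curve(st$init, s_values = unique(round(10^seq(0.3, 2.2, 0.1))))
  nu_fit <- fit_power_law(rc$s, rc$r, c(8, 64))$exponent
  bound <- delta_eq_analytic(n_loci(st$traj), nu_fit)
  expect_gt(max(d$delta), 0)
  expect_lt(max(d$delta), bound)
})

test_that("per-locus exponents are heterogeneous and active loci move more", {
  st <- collapsed_state()
  idx <- round(seq(8, 248, length.out = 20))
  betas <- vapply(idx, function(i) {
    fit_diffusion_exponent(msd_locus(st$traj, i, lags = log_lags(st$traj)),
                           c(10, 150))$beta
  }, numeric(1))
  expect_gt(sd(betas), 0.005)
})
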