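test_that("activity profiles map labels to noise multipliers", {
  expect_equal(make_activity_profile(uniform_annotation(4, "B3")),
               rep(1, 4))
  ann <- chrom_annotation(c("A1", "B3", "A2"))
  expect_equal(make_activity_profile(ann), c(2, 1, 2))
  expect_equal(make_activity_profile(ann, activity_spec(variance_multiplier = 1)),
               rep(1, 3))
  expect_equal(make_activity_profile(ann, activity_spec("B3", 3)), c(1, 3, 1))
  expect_error(activity_spec("A9"), "unknown")
})

test_that("a free bead diffuses with MSD = 6 D0 t and doubled variance doubles it", {
  ann <- uniform_annotation(1)
  par <- free_params()
  lags <- c(1, 2, 5)
  ratios <- sapply(1:100, function(s) {
    tr <- brownian_run(matrix(0, 1, 3), ann, par, t_total = 50, dt = 0.01,
                       frame_interval = 0.5, seed = s, cap_reject = 1e9)
    msd_locus(tr, 1, lags = lags)$value / (6 * lags)
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
  ratios2 <- sapply(1:100, function(s) {
    tr <- brownian_run(matrix(0, 1, 3), ann, par, activity_profile = 2,
                       t_total = 50, dt = 0.01, frame_interval = 0.5,
                       seed = 1000 + s, cap_reject = 1e9)
    msd_locus(tr, 1, lags = lags)$value / (6 * lags)
  })
  expect_lt(abs(mean(ratios2) / mean(ratios) - 2), 0.1)
})

test_that("trajectories are bit-reproducible and reject invalid stepping", {
  N <- 16
  ann <- uniform_annotation(N)
  par <- chrom_params(N)
  init <- make_collapsed_fixture(N, 0.1, seed = 1)
  t1 <- brownian_run(init, ann, par, t_total = 2, dt = 1e-3,
                     frame_interval = 0.1, seed = 3)
  t2 <- brownian_run(init, ann, par, t_total = 2, dt = 1e-3,
                     frame_interval = 0.1, seed = 3)
  expect_identical(t1$frames, t2$frames)
  expect_false(identical(
    t1$frames,
    brownian_run(init, ann, par, t_total = 2, dt = 1e-3,
                 frame_interval = 0.1, seed = 4)$frames))
  # dt above the stability cap and non-commensurate frame interval
  expect_error(brownian_run(init, ann, par, t_total = 1, dt = 0.01,
                            frame_interval = 0.1), "stability cap")
  expect_error(brownian_run(init, ann, par, t_total = 1, dt = 1e-3,
                            frame_interval = 0.00037), "multiple")
})

test_that("confined heteropolymer trajectories keep chain integrity", {
  N <- 64
  ann <- generate_annotation(N, 8, seed = 21)
  ann <- generate_loops(ann, 6, 4, 30, seed = 22)
  par <- chrom_params(N)
  init <- make_collapsed_fixture(N, 0.1, seed = 23)
  tr <- brownian_run(init, ann, par, t_total = 100, dt = 1e-3,
                     frame_interval = 0.01, seed = 24) # 10^4 frames
  expect_equal(n_frames(tr), 10001)
  worst_bond <- 0
  worst_pair <- Inf
  for (t in seq_len(n_frames(tr))) {
    x <- frame_at(tr, t)
    bl <- sqrt(rowSums((x[-1, ] - x[-N, ])^2))
    worst_bond <- max(worst_bond, max(bl))
    if (t %% 10 == 1) { # pair scan subsampled for cost
      d <- as.matrix(dist(x))
      worst_pair <- min(worst_pair, min(d[abs(row(d) - col(d)) >= 2]))
    }
  }
  expect_lt(worst_bond, 1.5)
  expect_gt(worst_pair, 0.6)
})

test_that("centre of mass of a free chain diffuses with D0/N", {
  N <- 16
  ann <- uniform_annotation(N)
  par <- rouse_params()
  lags <- c(5, 10, 20, 40)
  vals <- rowMeans(sapply(1:3, function(s) {
    init <- make_rouse_ensemble(N, 1, 1, seed = s)[[1]]
    tr <- brownian_run(init, ann, par, t_total = 4000, dt = 0.02,
                       frame_interval = 1, seed = 30 + s,
                       cap_drift = 1, cap_reject = 1e9)
    msd_aggregate(tr, "com", lags = lags)$value
  }))
  slope <- coef(lm(vals ~ 0 + lags))[1]
  expect_equal(unname(slope), 6 / N, tolerance = 0.05)
})

test_that("passive bond lengths follow the Boltzmann distribution (detailed balance)", {
  ann <- uniform_annotation(2)
  par <- free_params(bond_k = 200, bond_r0 = 1)
  tr <- brownian_run(rbind(c(0, 0, 0), c(1, 0, 0)), ann, par,
                     t_total = 2000, dt = 2.5e-4, frame_interval = 1, seed = 9)
  r <- vapply(seq_len(n_frames(tr)), function(t) {
    x <- frame_at(tr, t)
    sqrt(sum((x[2, ] - x[1, ])^2))
  }, numeric(1))
  r <- r[-1]
  # exact Boltzmann CDF for p(r) propto r^2 exp(-k/2 (r-1)^2)
  grid <- seq(0.5, 1.5, length.out = 4000)
  dens <- grid^2 * exp(-0.5 * 200 * (grid - 1)^2)
  cdf <- cumsum(dens) / sum(dens)
  pfun <- stats::approxfun(grid, cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(r, pfun))
  expect_gt(ks$p.value, 0.01)
})

test_that("the Langevin sampler thermalises velocities and collapses extended chains", {
  # equipartition on a force-free pair: velocity variance = kT/m = 1
  ann <- uniform_annotation(2)
  par <- free_params(bond_k = 0)
  out <- langevin_sample(rbind(c(0, 0, 0), c(5, 0, 0)), ann, par,
                         n_samples = 400, spacing = 1, burn_in = 5,
                         seed = 11, return_velocities = TRUE)
  v <- unlist(lapply(out$velocities, as.vector))
  expect_equal(mean(v^2), 1, tolerance = 3 * sd(v^2) / sqrt(length(v)))
  # collapse: a 128-bead heteropolymer shrinks from a fully extended start
  N <- 128
  annh <- generate_annotation(N, 10, seed = 31)
  parh <- chrom_params(N)
  rg <- function(m) sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  ss <- langevin_sample(extended_chain(N), annh, parh, n_samples = 1,
                        spacing = 1, burn_in = 100, seed = 32)
  expect_lt(rg(ss[[1]]), 0.5 * rg(extended_chain(N)))
  expect_true(all(is.finite(ss[[1]])))
  # determinism
  s2 <- langevin_sample(extended_chain(N), annh, parh, n_samples = 1,
                        spacing = 1, burn_in = 100, seed = 32)
  expect_identical(ss, s2)
})
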