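test_that("DRMS is a rigid-motion-invariant metric with the expected hand value", {
  set.seed(5)
  A <- random_conformation(10)
  expect_equal(drms(A, A), 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(drms(A, sweep(A %*% R, 2, c(3, -2, 7))), 0, tolerance = 1e-12)
  # collinear hand example: beads at 0,1,2 vs 0,1,3
  A3 <- cbind(0, 0, c(0, 1, 2))
  B3 <- cbind(0, 0, c(0, 1, 3))
  expect_equal(drms(A3, B3), sqrt(2 / 3), tolerance = 1e-12)
  # symmetry and triangle inequality on random conformations
  for (k in 1:50) {
    x <- random_conformation(8)
    y <- random_conformation(8)
    expect_equal(drms(x, y), drms(y, x))
  }
  for (k in 1:100) {
    x <- random_conformation(6)
    y <- random_conformation(6)
    z <- random_conformation(6)
    expect_lte(drms(x, z), drms(x, y) + drms(y, z) + 1e-12)
  }
  expect_error(drms(A, random_conformation(9)), "bead count")
})

test_that("the DRMS matrix matches elementwise evaluation", {
  set.seed(6)
  ens <- lapply(1:6, function(k) random_conformation(7))
  M <- drms_matrix(ens)
  expect_equal(drms_matrix(ens[1]), matrix(0, 1, 1))
  expect_identical(M, t(M))
  expect_equal(diag(M), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(M[i, j], drms(ens[[i]], ens[[j]]))
})

test_that("complete-linkage clustering matches the exhaustive oracle", {
  # two identical conformations: one cluster
  set.seed(7)
  x <- random_conformation(5)
  ct0 <- cluster_hierarchical(drms_matrix(list(x, x)), D_c = 0.5)
  expect_equal(length(unique(ct0$clusters)), 1)
  # hand-checkable 3-point matrix
  dm <- matrix(c(0, 1, 9, 1, 0, 9, 9, 9, 0), 3, 3)
  ct <- cluster_hierarchical(dm, D_c = 2)
  expect_equal(canonical_clusters(ct$clusters), list(c(1, 2), 3))
  # random ensembles against the naive oracle
  for (k in 1:5) {
    ens <- lapply(1:8, function(i) random_conformation(6))
    dmat <- drms_matrix(ens)
    D_c <- stats::median(dmat[upper.tri(dmat)])
    got <- cluster_hierarchical(dmat, D_c)$clusters
    expect_equal(canonical_clusters(got),
                 canonical_clusters(complete_linkage_oracle(dmat, D_c)))
  }
  # merge heights nondecreasing; newick serialisation parses in ape
  ens <- lapply(1:7, function(i) random_conformation(6))
  ct2 <- cluster_hierarchical(drms_matrix(ens), 1)
  expect_true(all(diff(ct2$tree$height) >= 0))
  tr <- ape::read.tree(text = as_newick(ct2))
  expect_equal(sort(tr$tip.label), as.character(1:7))
  expect_error(cluster_hierarchical(matrix(c(0, 1, 2, 0), 2, 2), 1),
               "symmetric")
})

test_that("quality-threshold clustering removes the largest admissible cluster first", {
  dm <- matrix(c(0, 1, 9, 1, 0, 9, 9, 9, 0), 3, 3)
  qt <- cluster_qt(dm, d_c = 2)
  expect_equal(qt, list(c(1, 2), 3))
  # all singletons when every distance exceeds d_c
  dm2 <- matrix(5, 4, 4); diag(dm2) <- 0
  qt2 <- cluster_qt(dm2, d_c = 2)
  expect_equal(lengths(qt2), rep(1L, 4))
  # disjoint cover
  set.seed(8)
  ens <- lapply(1:8, function(i) random_conformation(6))
  dmat <- drms_matrix(ens)
  qt3 <- cluster_qt(dmat, stats::median(dmat[upper.tri(dmat)]))
  expect_equal(sort(unlist(qt3)), 1:8)
  # every cluster's diameter is below d_c
  d_c <- stats::median(dmat[upper.tri(dmat)])
  for (cl in qt3)
    if (length(cl) > 1) expect_lt(max(dmat[cl, cl]), d_c)
})

test_that("cluster centroids minimise the intra-cluster distance sum", {
  expect_equal(cluster_centroids(matrix(0, 1, 1), list(1)), 1L)
  dm <- matrix(0, 3, 3)
  dm[1, 2] <- dm[2, 1] <- 1
  dm[1, 3] <- dm[3, 1] <- 1
  dm[2, 3] <- dm[3, 2] <- 3
  expect_equal(cluster_centroids(dm, list(1:3)), 1L)
  # invariant under member reordering; ties break to the smallest index
  expect_equal(cluster_centroids(dm, list(c(3, 1, 2))), 1L)
  expect_equal(cluster_centroids(matrix(0, 2, 2), list(1:2)), 1L)
})

test_that("contact maps and P(s) match hand summation", {
  conf <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  cm <- contact_map_from_ensemble(list(conf), mu = 3, r_c = 1.5)
  expect_equal(cm$matrix[1, 2], 0.5)
  ps <- contact_probability_curve(cm)
  expect_equal(ps$p[ps$s == 1], 0.5)
  # 5-bead toy ensemble against direct averaging
  set.seed(9)
  ens <- lapply(1:4, function(k) random_conformation(5, sd = 1))
  cm5 <- contact_map_from_ensemble(ens, 3, 1.5)
  f <- function(r) 0.5 * (1 + tanh(3 * (1.5 - r)))
  for (s in 1:4) {
    hand <- mean(unlist(lapply(ens, function(cf)
      vapply(seq_len(5 - s), function(i)
        f(sqrt(sum((cf[i + s, ] - cf[i, ])^2))), numeric(1)))))
    expect_equal(contact_probability_curve(cm5)$p[s], hand, tolerance = 1e-12)
  }
  expect_true(all(cm5$matrix >= 0 & cm5$matrix <= 1))
  expect_equal(contact_probability_direct(ens, 1:4, 3, 1.5)$p,
               contact_probability_curve(cm5)$p)
})

test_that("R(s) and power-law fitting recover known scaling laws", {
  x <- 1:100
  f <- fit_power_law(x, 3 * x^0.75, c(1, 100))
  expect_equal(f$exponent, 0.75, tolerance = 1e-12)
  expect_equal(f$prefactor, 3, tolerance = 1e-10)
  expect_error(fit_power_law(1:2, c(1, 2), c(1, 2)), "3 points")
  ens <- make_rouse_ensemble(200, 1, 2000, seed = 10)
  rc <- ree_curve(ens, s_values = unique(round(10^seq(0.3, 2.2, 0.1))))
  nu <- fit_power_law(rc$s, rc$r, c(4, 64))$exponent
  expect_lt(abs(nu - 0.5), 0.03)
})

test_that("radial density profiles normalise to the subset mean density", {
  set.seed(11)
  # uniform beads in a ball: flat profile near 1
  u <- runif(4000)^(1 / 3) * 5
  dirs <- matrix(rnorm(12000), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ens <- list(dirs * u)
  rd <- radial_density(ens, n_bins = 8, r_max = 5)
  inner <- rd$density[rd$n > 100]
  expect_true(all(abs(inner - 1) < 0.2))
  # all beads on one shell
  shell <- dirs[1:500, ] * 5
  rd2 <- radial_density(list(shell), n_bins = 10, r_max = 6)
  expect_equal(sum(rd2$n > 0), 1)
  # subset = all equals the unrestricted profile
  ann <- uniform_annotation(4000, "B2")
  rd3 <- radial_density(ens, ann, subset = "B2", n_bins = 8, r_max = 5)
  expect_equal(rd3$density, rd$density)
})

test_that("P(s) of the ideal-chain ensemble decays as s^(-3/2)", {
  ens <- make_rouse_ensemble(512, 1, 2000, seed = 12)
  ps <- contact_probability_direct(ens, unique(round(10^seq(1.3, 2.5, 0.06))))
  slope <- fit_power_law(ps$s, ps$p, c(30, 300))$exponent
  expect_lt(abs(slope + 1.5), 0.1)
})
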