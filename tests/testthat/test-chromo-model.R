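test_that("contact indicator is a proper sigmoid with midpoint r_c", {
  expect_equal(contact_indicator(1.5, mu = 3, r_c = 1.5), 0.5)
  expect_gt(contact_indicator(0, mu = 3, r_c = 1.5), 0.99)
  expect_lt(contact_indicator(15, mu = 3, r_c = 1.5), 1e-10)
  r <- seq(0, 7.5, length.out = 100)
  expect_true(all(diff(contact_indicator(r)) < 0))
  # doubling mu sharpens the sigmoid away from the midpoint
  r2 <- r[abs(r - 1.5) > 1e-6]
  expect_true(all(abs(contact_indicator(r2, mu = 6) - 0.5) >
                    abs(contact_indicator(r2, mu = 3) - 0.5)))
  expect_error(contact_indicator(-1), "nonnegative")
})

test_that("decomposed energies match a brute-force double-loop oracle", {
  set.seed(42)
  N <- 20
  ann <- generate_annotation(N, 3, seed = 5)
  ann <- generate_loops(ann, 3, 2, 10, seed = 6)
  par <- chrom_params(N)
  conf <- random_conformation(N)
  e <- energy_decomposed(conf, ann, par)
  oracle <- energy_oracle(conf, ann, par)
  expect_equal(unlist(e[names(oracle)]), oracle, tolerance = 1e-10)
  expect_equal(e$total, sum(oracle), tolerance = 1e-12)
})

test_that("trivial conformations produce the expected term values", {
  # two beads at rest length, inside sphere, NA labels with zero couplings
  ann <- uniform_annotation(2)
  par <- free_params(bond_k = 100, wall_k = 100, R_s = 10)
  e <- energy_decomposed(rbind(c(0, 0, 0), c(1, 0, 0)), ann, par)
  expect_equal(e$type, 0)
  expect_equal(e$loop, 0)
  expect_equal(e$ideal, 0)
  expect_equal(e$confinement, 0)
  expect_equal(e$bonded, 0)
  # loop midpoint: three beads with loop (0,2) at r = r_c
  ann3 <- chrom_annotation(rep("NA", 3), loops = cbind(0L, 2L))
  par3 <- chrom_params(R_s = 50, wall_k = 0, type_matrix = matrix(0, 6, 6),
                       ideal_gamma = numeric(2), loop_eps = -2)
  conf3 <- rbind(c(0, 0, 0), c(0.75, 1, 0), c(1.5, 0, 0))
  e3 <- energy_decomposed(conf3, ann3, par3)
  expect_equal(e3$loop, -2 * 0.5, tolerance = 1e-12)
  # size mismatch
  expect_error(energy_decomposed(random_conformation(4), ann3, par3), "loci")
})

test_that("forces are the exact negative gradient of the energy", {
  set.seed(7)
  N <- 12
  ann <- generate_annotation(N, 3, seed = 7)
  ann <- generate_loops(ann, 2, 2, 8, seed = 8)
  par <- chrom_params(N, R_s = 2)
  conf <- random_conformation(N, sd = 1)
  F <- total_force(conf, ann, par)
  h <- 1e-5
  scale <- max(abs(F))
  for (i in seq_len(N)) for (c in 1:3) {
    cp <- conf; cp[i, c] <- cp[i, c] + h
    cm <- conf; cm[i, c] <- cm[i, c] - h
    fd <- -(energy_decomposed(cp, ann, par)$total -
              energy_decomposed(cm, ann, par)$total) / (2 * h)
    expect_lt(abs(F[i, c] - fd), 1e-4 * scale)
  }
  # isolated bead at the origin inside the sphere: zero force
  F1 <- total_force(matrix(0, 1, 3), uniform_annotation(1), par)
  expect_equal(unname(F1), matrix(0, 1, 3))
  # internal terms are translation invariant: zero net force without wall
  F2 <- total_force(conf, ann, par, confine = FALSE)
  expect_lt(max(abs(colSums(F2))), 1e-10)
})

test_that("energy is invariant under rigid transforms", {
  set.seed(1)
  N <- 15
  ann <- generate_annotation(N, 4, seed = 9)
  par <- chrom_params(N)
  conf <- random_conformation(N, sd = 1.5)
  e0 <- energy_decomposed(conf, ann, par, confine = FALSE)$total
  for (k in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                   0, -sin(th[1]), cos(th[1])), 3, 3)
    Rz <- matrix(c(cos(th[2]), sin(th[2]), 0, -sin(th[2]), cos(th[2]), 0,
                   0, 0, 1), 3, 3)
    tv <- rnorm(3, sd = 5)
    conf2 <- sweep(conf %*% Rx %*% Rz, 2, -tv)
    e1 <- energy_decomposed(conf2, ann, par, confine = FALSE)$total
    expect_equal(e1, e0, tolerance = 1e-8)
  }
})

test_that("zeroing heteropolymer couplings reduces the model to a confined homopolymer", {
  N <- 25
  ann <- generate_annotation(N, 4, seed = 11)
  ann <- generate_loops(ann, 4, 2, 10, seed = 12)
  par <- chrom_params(N, type_matrix = matrix(0, 6, 6),
                      ideal_gamma = rep(0, 500), loop_eps = 0)
  e <- energy_decomposed(random_conformation(N), ann, par)
  expect_identical(e$type, 0)
  expect_identical(e$loop, 0)
  expect_identical(e$ideal, 0)
})

test_that("model parameters round-trip through the config file", {
  par <- chrom_params(100, loop_eps = -1.25, mu = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(par, path)
  par2 <- read_params(path)
  expect_equal(par2$type_matrix, par$type_matrix)
  expect_equal(par2$ideal_gamma, par$ideal_gamma)
  expect_equal(par2$loop_eps, par$loop_eps)
  expect_equal(par2$R_s, par$R_s)
  expect_error(chrom_params(10, type_matrix = matrix(1:36 / 36, 6, 6)),
               "symmetric")
})
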