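test_that("mixing rules follow the localized vs distributed conventions", {
  hp <- hp_forcefield("HP", lambda_H = 1)
  expect_equal(hp$lambda_table["H", "H"], 1)
  expect_equal(hp$lambda_table["H", "P"], 0)
  expect_equal(hp$lambda_table["P", "P"], 0)

  hpp <- hp_forcefield("HP+", lambda_H = 1)
  expect_equal(hpp$lambda_table["H", "P"], 0.5)
  expect_equal(hpp$lambda_table["P", "H"], 0.5)
  expect_equal(hpp$lambda_table["P", "P"], 0)

  hp0 <- hp_forcefield("HP+", lambda_H = 0)
  expect_true(all(hp0$lambda_table == 0))
  expect_error(hp_forcefield("HP", lambda_H = -0.1), "lambda_H")

  # stated defaults
  expect_equal(hp$epsilon, 0.2)
  expect_equal(hp$sigma, 0.5)
  expect_equal(hp$k_b, 2000)
  expect_equal(hp$r0, 0.38)
})

test_that("composition rescaling of the H hydropathy is a/(1 - X_P)", {
  expect_equal(scaled_lambda_H(1, 0), 1)
  expect_equal(scaled_lambda_H(1, 0.5), 2)
  expect_equal(scaled_lambda_H(0.8, 0.75), 3.2)
  expect_error(scaled_lambda_H(1, 1), "X_P")
})

test_that("pair potential reduces to WCA at lambda = 0 and LJ at lambda = 1", {
  ff <- hp_forcefield("HP", lambda_H = 1)
  rmin <- 2^(1 / 6) * ff$sigma
  # full-LJ limit: minimum of depth epsilon at rmin, LJ values everywhere
  expect_equal(pair_energy(rmin, 1, ff), -0.2, tolerance = 1e-12)
  rs <- seq(0.45, ff$r_cut - 1e-9, by = 0.01)
  ulj <- 4 * ff$epsilon * ((ff$sigma / rs)^12 - (ff$sigma / rs)^6)
  expect_equal(pair_energy(rs, 1, ff), ulj, tolerance = 1e-12)
  # WCA limit: zero at and beyond rmin, shifted repulsion inside
  expect_equal(pair_energy(rmin, 0, ff), 0, tolerance = 1e-12)
  expect_true(all(pair_energy(seq(rmin, 2, by = 0.01), 0, ff) == 0))
  expect_equal(pair_energy(ff$sigma, 0, ff), ff$epsilon, tolerance = 1e-12)
  # mid lambda: U(sigma) = (1 - lambda) * eps since U_LJ(sigma) = 0
  expect_equal(pair_energy(ff$sigma, 0.5, ff), 0.1, tolerance = 1e-12)
  expect_error(pair_energy(0, 1, ff), "positive")
})

test_that("pair potential is continuous and its well depth is lambda * eps", {
  ff <- hp_forcefield("HP", lambda_H = 1)
  rmin <- 2^(1 / 6) * ff$sigma
  for (lam in c(0, 0.2, 0.5, 0.8, 1)) {
    expect_equal(pair_energy(rmin - 1e-10, lam, ff),
                 pair_energy(rmin + 1e-10, lam, ff), tolerance = 1e-7)
    expect_equal(min(pair_energy(seq(0.5, 2, by = 1e-4), lam, ff)),
                 -lam * ff$epsilon, tolerance = 1e-6)
  }
  # deeper attraction with growing lambda at fixed tail distance
  u_tail <- vapply(c(0.1, 0.4, 0.7, 1), function(l)
    pair_energy(0.7, l, ff), numeric(1))
  expect_true(all(diff(u_tail) < 0))
  # well depth in thermal units ~ 0.3 kT at 300 K
  expect_equal(0.2 / (0.0019872041 * 300), 0.336, tolerance = 2e-3)
})

test_that("pair force is the negative radial derivative of the energy", {
  ff <- hp_forcefield("HP", lambda_H = 1)
  h <- 1e-7
  for (lam in c(0, 0.5, 1)) {
    rs <- c(0.47, 0.53, 2^(1 / 6) * 0.5 + 0.01, 0.8, 1.4)
    num <- -(pair_energy(rs + h, lam, ff) - pair_energy(rs - h, lam, ff)) / (2 * h)
    expect_equal(pair_force(rs, lam, ff), num, tolerance = 1e-5)
  }
})

test_that("bond energy is harmonic and symmetric about r0", {
  ff <- hp_forcefield("HP")
  expect_equal(bond_energy(ff$r0, ff), 0)
  expect_equal(bond_energy(ff$r0 + 0.01, ff), 0.2, tolerance = 1e-12)
  expect_equal(bond_energy(ff$r0 - 0.01, ff), 0.2, tolerance = 1e-12)
})

test_that("cell-list nonbonded energy matches the all-pairs oracle", {
  ff <- hp_forcefield("HP+", lambda_H = 0.9)
  # two isolated P monomers never attract
  st <- hp_state(rbind(c(1, 1, 1), c(1, 1, 1 + 0.6)), matrix(0, 2, 3),
                 c("P", "P"), 1:2, c(6, 6, 6))
  expect_equal(system_nonbonded_energy(st, ff), 0)
  # two H monomers at the minimum
  st2 <- hp_state(rbind(c(1, 1, 1), c(1, 1, 1 + 2^(1 / 6) * 0.5)),
                  matrix(0, 2, 3), c("H", "H"), 1:2, c(6, 6, 6))
  ff1 <- hp_forcefield("HP", lambda_H = 1)
  expect_equal(system_nonbonded_energy(st2, ff1), -0.2, tolerance = 1e-12)
  # random configurations vs brute force, including bonded exclusions
  set.seed(31)
  for (rep in 1:5) {
    n <- 10
    pos <- cbind(runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 4))
    types <- sample(c("H", "P"), n, replace = TRUE)
    st3 <- hp_state(pos, matrix(0, n, 3), types,
                    rep(1:2, each = 5), c(4.5, 4.5, 4.5))
    expect_equal(system_nonbonded_energy(st3, ff),
                 brute_nb_energy(st3, ff), tolerance = 1e-10)
  }
  # larger system through the cell-list path
  set.seed(32)
  n <- 100
  pos <- cbind(runif(n, 0, 7), runif(n, 0, 7), runif(n, 0, 7))
  st4 <- hp_state(pos, matrix(0, n, 3), sample(c("H", "P"), n, TRUE),
                  rep(1:10, each = 10), c(7, 7, 7))
  expect_equal(system_nonbonded_energy(st4, ff), brute_nb_energy(st4, ff),
               tolerance = 1e-10)
})

test_that("force-field serialization round-trips through a plain list", {
  ff <- hp_forcefield("HP+", lambda_H = 0.77)
  back <- ff_from_list(ff_to_list(ff))
  expect_equal(back, ff)
})
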