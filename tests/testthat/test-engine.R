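test_that("configuration builders honour their geometric contracts", {
  seq <- seq_at(0.25)
  ff <- hp_forcefield("HP")
  st <- build_single_chain(seq, ff = ff, seed = 3)
  expect_equal(nrow(st$positions), 20)
  bl <- sqrt(rowSums((st$positions[-1, ] - st$positions[-20, ])^2))
  expect_length(bl, 19)
  expect_true(all(abs(bl - ff$r0) <= 0.05))

  st2 <- build_two_chains(seq, r_com = 5, box = c(25, 25, 25), seed = 4)
  comA <- colMeans(st2$positions[1:20, ])
  comB <- colMeans(st2$positions[21:40, ])
  expect_equal(sqrt(sum((comB - comA)^2)), 5, tolerance = 1e-9)

  sl <- build_slab(seq, n_chains = 30, box = c(8, 8, 24), seed = 5)
  expect_equal(nrow(sl$positions), 600)
  expect_equal(length(unique(sl$chain_ids)), 30)
  zw <- sl$positions[, 3]
  expect_true(all(zw > 24 * 0.15 & zw < 24 * 0.85))  # central z-region
  d <- as.matrix(dist(sl$positions)); diag(d) <- Inf
  # nonbonded minimum separation: bonded neighbours may sit at r0
  expect_true(min(d) >= 0.38 - 1e-9)
  nb <- d
  for (i in which(sl$chain_ids[-1] == sl$chain_ids[-600])) {
    nb[i, i + 1] <- Inf; nb[i + 1, i] <- Inf
  }
  expect_true(min(nb) >= 0.8 * 0.5 - 1e-9)

  cu <- build_cubic(seq, n_chains = 27, edge = 30, seed = 6)
  expect_equal(nrow(cu$positions), 540)
  expect_equal(cu$box, c(30, 30, 30))
})

test_that("neighbour lists agree with the all-pairs oracle", {
  box <- c(10, 10, 10)
  st <- hp_state(rbind(c(1, 1, 1), c(1, 1, 1 + 1.8)), matrix(0, 2, 3),
                 c("H", "H"), 1:2, box)
  expect_equal(nrow(neighbor_pairs(st, 2.0)), 1)
  st2 <- hp_state(rbind(c(1, 1, 1), c(1, 1, 1 + 2.6)), matrix(0, 2, 3),
                  c("H", "H"), 1:2, box)
  expect_equal(nrow(neighbor_pairs(st2, 2.0, skin = 0.3)), 0)
  expect_error(neighbor_pairs(st, 5.1), "geometry")

  set.seed(41)
  for (rep in 1:3) {
    n <- 50
    pos <- cbind(runif(n, 0, 6), runif(n, 0, 6), runif(n, 0, 6))
    st3 <- hp_state(pos, matrix(0, n, 3), rep("H", n), 1:n, c(6, 6, 6))
    got <- neighbor_pairs(st3, 1.5)
    want <- which(upper.tri(diag(n)), arr.ind = TRUE)
    d2 <- apply(want, 1, function(ij) {
      dd <- pos[ij[1], ] - pos[ij[2], ]
      dd <- dd - 6 * round(dd / 6)
      sum(dd^2)
    })
    want <- want[d2 <= 1.5^2, , drop = FALSE]
    key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    expect_identical(key(got), key(unname(want)))
  }
})

test_that("langevin trajectories are deterministic in the seed", {
  seq <- seq_at(0)
  ff <- hp_forcefield("HP", lambda_H = 1)
  st <- build_single_chain(seq, ff = ff, seed = 7)
  t1 <- run_langevin(st, ff, n_steps = 2e3, sample_every = 100, seed = 99)
  t2 <- run_langevin(st, ff, n_steps = 2e3, sample_every = 100, seed = 99)
  t3 <- run_langevin(st, ff, n_steps = 2e3, sample_every = 100, seed = 100)
  expect_identical(t1$frames, t2$frames)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("free-particle diffusion follows the Einstein relation", {
  # 125 non-interacting polar beads on a wide grid: MSD slope = 6 kT / gamma
  g <- as.matrix(expand.grid(x = 1:5, y = 1:5, z = 1:5)) * 9 - 4.5
  st <- hp_state(g, matrix(0, 125, 3), rep("P", 125), 1:125, c(45, 45, 45))
  ff <- hp_forcefield("HP", lambda_H = 0)
  st$velocities <- matrix(rnorm(375, sd = sqrt(0.59616 * 4.184e-6 / 100)), ncol = 3)
  tr <- run_langevin(st, ff, n_steps = 4e4, sample_every = 100, seed = 5)
  # time-averaged MSD at two long lags (>> m/gamma = 1000 fs)
  msd_at <- function(lag_frames) {
    nf <- n_frames(tr)
    disp <- tr$frames[, , (1 + lag_frames):nf, drop = FALSE] -
      tr$frames[, , 1:(nf - lag_frames), drop = FALSE]
    mean(apply(disp^2, 3, sum) / 125)
  }
  dt_frame <- 100 * 10                       # fs between frames
  m1 <- msd_at(5); m2 <- msd_at(20)
  slope <- (m2 - m1) / (15 * dt_frame)
  D <- 0.0019872041 * 300 * 4.184e-6 / 0.1   # kT/gamma in nm^2/fs
  expect_equal(slope, 6 * D, tolerance = 0.05)
})

test_that("bonded dimer samples the Boltzmann bond-length distribution", {
  ff <- hp_forcefield("HP", lambda_H = 1)
  pos <- rbind(c(5, 5, 5), c(5, 5, 5.38))
  st <- hp_state(pos, matrix(0, 2, 3), c("H", "H"), c(1, 1), c(10, 10, 10))
  tr <- run_langevin(st, ff, n_steps = 3e5, sample_every = 30, seed = 21)
  r <- vapply(seq_len(n_frames(tr)), function(f)
    sqrt(sum((tr$frames[1, , f] - tr$frames[2, , f])^2)), numeric(1))
  r <- r[-(1:500)]
  # quadrature oracle: p(r) ~ r^2 exp(-k (r - r0)^2 / kT)
  kT <- 0.0019872041 * 300
  grid <- seq(0.3, 0.46, by = 1e-4)
  wts <- grid^2 * exp(-2000 * (grid - 0.38)^2 / kT)
  wts <- wts / sum(wts)
  mean_or <- sum(grid * wts)
  sd_or <- sqrt(sum(grid^2 * wts) - mean_or^2)
  expect_equal(mean(r), mean_or, tolerance = 0.003)
  expect_equal(sd(r), sd_or, tolerance = 0.05)
  # binned densities against the quadrature, as total-variation distance
  brks <- seq(0.33, 0.43, by = 0.01)
  pr <- hist(pmin(pmax(r, 0.33), 0.43), breaks = brks, plot = FALSE)$counts
  pr <- pr / sum(pr)
  po <- vapply(seq_len(length(brks) - 1), function(b)
    sum(wts[grid >= brks[b] & grid < brks[b + 1]]), numeric(1))
  expect_lt(sum(abs(pr - po / sum(po))) / 2, 0.03)
})

test_that("velocity decorrelation time is m/gamma for free particles", {
  # position increments of free beads decay with the momentum relaxation time
  st <- hp_state(matrix(22.5, 1, 3), matrix(0, 1, 3), "P", 1L, c(45, 45, 45))
  ff <- hp_forcefield("HP", lambda_H = 0)
  tr <- run_langevin(st, ff, n_steps = 5e5, sample_every = 10, seed = 8)
  x <- tr$frames[1, 1, ]
  dx <- diff(x)
  a <- acf(dx, lag.max = 15, plot = FALSE)$acf[, 1, 1]
  lags <- (0:15) * 100                      # fs
  # fit the exponential tail at lags >= 1 (high signal-to-noise region);
  # the intercept absorbs the finite-window amplitude factor
  keep <- 2:13
  tau <- -1 / coef(lm(log(a[keep]) ~ lags[keep]))[2]
  expect_equal(unname(tau), 100 / 0.1, tolerance = 0.1)
})

test_that("thermostat holds the kinetic temperature at the set point", {
  seq <- seq_at(0.5)
  ff <- hp_forcefield("HP+", lambda_H = 1)
  st <- build_single_chain(seq, ff = ff, seed = 9)
  tr <- run_langevin(st, ff, n_steps = 1e5, sample_every = 100, seed = 10)
  expect_equal(mean(kinetic_temperature(tr)), 300, tolerance = 0.02)
})

test_that("gamma = 0 degenerates to energy-conserving velocity Verlet", {
  seq <- seq_at(0)
  ff <- hp_forcefield("HP", lambda_H = 1)
  st <- build_single_chain(seq, ff = ff, seed = 12)
  st$velocities <- maxwell_velocities <- matrix(rnorm(60, sd = 1.6e-4), ncol = 3)
  tr <- run_langevin(st, ff, n_steps = 1e5, dt = 1, gamma = 0,
                     sample_every = 1000, seed = 1)
  etot <- tr$ke + tr$u_nb + tr$u_bond
  # secular drift (fitted slope over the run), not the bounded dt^2 wobble
  drift <- abs(unname(coef(lm(etot ~ seq_along(etot)))[2])) * length(etot) / 20
  expect_lt(drift, 1e-4)   # kcal/mol per particle over 1e5 steps at 1 fs
})

test_that("extended-XYZ round trip preserves frames, box and topology", {
  seq <- seq_at(0.25)
  ff <- hp_forcefield("HP+", lambda_H = 1)
  st <- build_single_chain(seq, ff = ff, seed = 13)
  tr <- run_langevin(st, ff, n_steps = 1e3, sample_every = 200, seed = 14)
  path <- tempfile(fileext = ".xyz")
  write_xyz(tr, path)
  back <- read_xyz(path)
  expect_equal(length(back$frames), n_frames(tr))
  expect_equal(back$box, tr$box)
  expect_equal(back$types, tr$types)
  expect_equal(back$chain_ids, tr$chain_ids)
  expect_equal(back$frames[[3]], unname(frame_positions(tr, 3)),
               tolerance = 1e-6)
})
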