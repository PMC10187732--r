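# synthetic slab/gas/droplet configuration generators used as oracles

synthetic_traj <- function(sampler, n_beads, n_frames, box,
                           n_chains = n_beads / 20) {
  frames <- array(0, c(n_beads, 3, n_frames))
  for (f in seq_len(n_frames)) frames[, , f] <- sampler()
  fake_traj(frames, box, rep("H", n_beads),
            rep(seq_len(n_chains), each = n_beads / n_chains))
}

test_that("density profiles conserve mass and flatten for an ideal gas", {
  set.seed(61)
  box <- c(8, 8, 30)
  n <- 2000
  gas <- synthetic_traj(function()
    cbind(runif(n, 0, 8), runif(n, 0, 8), runif(n, 0, 30)), n, 25, box, 100)
  prof <- density_profile(gas, bin_width = 1, equil_frac = 0)
  total <- attr(prof, "total_concentration")
  # bin-integrated mass equals the system mass
  binvol <- 8 * 8 * 1
  expect_equal(sum(prof$conc) * binvol / 166.053907, n, tolerance = 1e-6)
  # flat within counting noise (sd across bins ~ sqrt(N_bin))
  expect_lt(sd(prof$conc) / mean(prof$conc), 0.15)
  expect_equal(mean(prof$conc), total, tolerance = 1e-6)

  # all mass in one bin: spike with exact conservation
  spike <- synthetic_traj(function()
    cbind(runif(50, 0, 8), runif(50, 0, 8), rep(15.2, 50)), 50, 3, box, 5)
  ps <- density_profile(spike, bin_width = 1, center = FALSE, equil_frac = 0)
  expect_equal(sum(ps$conc > 0), 1)
  expect_equal(sum(ps$conc) * binvol / 166.053907, 50, tolerance = 1e-6)
})

test_that("profiles from a known tanh construction recover its parameters", {
  set.seed(62)
  box <- c(8, 8, 30)
  c_d <- 600; c_l <- 10; z0 <- 4; dwd <- 0.8
  dens <- function(z) (c_d + c_l) / 2 - (c_d - c_l) / 2 * tanh((abs(z) - z0) / dwd)
  zs <- seq(-15, 15, by = 0.01)
  pz <- dens(zs); pz <- pz / sum(pz)
  n <- 4000
  sampler <- function() {
    z <- sample(zs, n, replace = TRUE, prob = pz) + 15  # to box coords
    cbind(runif(n, 0, 8), runif(n, 0, 8), z)
  }
  tr <- synthetic_traj(sampler, n, 40, box, 200)
  prof <- density_profile(tr, bin_width = 0.5, equil_frac = 0)
  cx <- extract_coexistence(prof)
  # scale construction to the simulated bead count
  scale <- n * 166.053907 / (64 * sum(dens(zs)) * 0.01)
  expect_equal(cx$c_dense, c_d * scale, tolerance = 0.02)
  expect_equal(cx$c_dilute, c_l * scale, tolerance = 0.25)
  expect_equal(cx$z0, z0, tolerance = 0.1)
})

test_that("interface extraction is exact on a step profile and rejects flat ones", {
  z <- seq(-14.75, 14.75, by = 0.5)
  step <- ifelse(abs(z) < 5, 600, 10)
  prof <- structure(tibble::tibble(z = z, conc = step, se = 1),
                    class = c("hp_profile", "tbl_df", "tbl", "data.frame"),
                    box = c(8, 8, 30), total_concentration = 120)
  cx <- extract_coexistence(prof)
  expect_equal(cx$c_dense, 600, tolerance = 1e-3)
  expect_equal(cx$c_dilute, 10, tolerance = 1e-2)
  flat <- structure(tibble::tibble(z = z, conc = rep(100, length(z)), se = 1),
                    class = c("hp_profile", "tbl_df", "tbl", "data.frame"),
                    box = c(8, 8, 30), total_concentration = 100)
  expect_error(extract_coexistence(flat), "classification error")
})

test_that("phase classifier separates slab, droplet and homogeneous states", {
  set.seed(63)
  box <- c(8, 8, 30)
  # slab: 98 chains densely packed in |z - 15| < 2 plus 2 vapour chains
  n_ch <- 100
  grid_com <- as.matrix(expand.grid(x = seq(0.7, 7.5, by = 1.32),
                                    y = seq(0.7, 7.5, by = 1.32),
                                    z = seq(13.2, 16.8, by = 1.2)))
  slab_sampler <- function() {
    com <- rbind(grid_com[seq_len(n_ch - 2), ] +
                   matrix(rnorm(3 * (n_ch - 2), sd = 0.1), ncol = 3),
                 cbind(runif(2, 0, 8), runif(2, 0, 8), runif(2, 0, 30)))
    com[rep(1:n_ch, each = 20), ] + matrix(rnorm(n_ch * 60, sd = 0.3),
                                           ncol = 3)
  }
  tr_slab <- synthetic_traj(slab_sampler, n_ch * 20, 12, box, n_ch)
  prof_slab <- density_profile(tr_slab, bin_width = 1, equil_frac = 0)
  csd_slab <- cluster_size_distribution(tr_slab, cutoff = 0.75, equil_frac = 0)
  expect_equal(classify_phase_state(prof_slab, csd_slab), "slab")

  # droplet: single compact sphere (parabolic profile, small cluster count)
  drop_sampler <- function() {
    n <- 30 * 20
    com <- cbind(runif(30, 3.2, 4.8), runif(30, 3.2, 4.8), runif(30, 14, 16))
    com[rep(1:30, each = 20), ] + matrix(rnorm(n * 3, sd = 0.3), ncol = 3)
  }
  # droplet plus free chains scattered in the gas phase
  mixed_sampler <- function() {
    drop <- drop_sampler()[1:400, ]
    free_com <- cbind(runif(10, 0, 8), runif(10, 0, 8), runif(10, 0, 30))
    free <- free_com[rep(1:10, each = 20), ] +
      matrix(rnorm(600, sd = 0.3), ncol = 3)
    rbind(drop, free)
  }
  tr_mix <- synthetic_traj(mixed_sampler, 600, 12, box, 30)
  csd_mix <- cluster_size_distribution(tr_mix, cutoff = 0.75, equil_frac = 0)
  prof_mix <- density_profile(tr_mix, bin_width = 1, equil_frac = 0)
  expect_lt(attr(csd_mix, "largest_fraction"), 0.9)
  expect_equal(classify_phase_state(prof_mix, csd_mix), "cluster")

  # homogeneous dilute gas
  gas <- synthetic_traj(function()
    cbind(runif(400, 0, 8), runif(400, 0, 8), runif(400, 0, 30)),
    400, 12, box, 20)
  prof_gas <- density_profile(gas, bin_width = 2, equil_frac = 0)
  csd_gas <- cluster_size_distribution(gas, cutoff = 0.75, equil_frac = 0)
  expect_equal(classify_phase_state(prof_gas, csd_gas), "homogeneous")
})

test_that("the H-H radial distribution is flat for an ideal gas and peaked for a pair", {
  set.seed(64)
  box <- c(10, 10, 10)
  tr <- synthetic_traj(function()
    cbind(runif(3000, 0, 10), runif(3000, 0, 10), runif(3000, 0, 10)),
    3000, 8, box, 150)
  g <- rdf_HH(tr, dr = 0.1, r_max = 3, equil_frac = 0)
  expect_equal(mean(g$g[g$r > 0.5]), 1, tolerance = 0.05)

  # fixed pair at distance d: single occupied bin at d
  pairpos <- rbind(c(5, 5, 5), c(5, 5, 6.23))
  trp <- fake_traj(array(rep(pairpos, 3), c(2, 3, 3)), box, c("H", "H"), 1:2)
  gp <- rdf_HH(trp, dr = 0.1, r_max = 3, equil_frac = 0)
  expect_equal(gp$r[which(gp$g > 0)], 1.25, tolerance = 0.05)

  trq <- fake_traj(array(rep(pairpos, 3), c(2, 3, 3)), box, c("P", "P"), 1:2)
  expect_error(rdf_HH(trq), "no H monomers")
})

test_that("chain clustering matches an independent graph-component oracle", {
  set.seed(65)
  # two far-apart chains are two singleton clusters
  seq <- seq_at(0)
  stA <- build_single_chain(seq, box = c(20, 20, 20), seed = 1)
  pos <- rbind(sweep(stA$positions, 2, c(5, 0, 0)),
               sweep(stA$positions, 2, c(-5, 0, 0)))
  st2 <- hp_state(pos, matrix(0, 40, 3), rep("H", 40), rep(1:2, each = 20),
                  c(20, 20, 20))
  expect_equal(cluster_chains(st2, cutoff = 0.75), c(1, 2))

  # random frames vs igraph connected components
  for (rep in 1:4) {
    n_ch <- 10
    com <- cbind(runif(n_ch, 0, 9), runif(n_ch, 0, 9), runif(n_ch, 0, 9))
    pos <- com[rep(1:n_ch, each = 20), ] + matrix(rnorm(n_ch * 60, sd = 0.5),
                                                  ncol = 3)
    st <- hp_state(pos, matrix(0, n_ch * 20, 3), rep("H", n_ch * 20),
                   rep(1:n_ch, each = 20), c(9, 9, 9))
    lab <- cluster_chains(st, cutoff = 0.75)
    # oracle: brute-force adjacency + igraph components
    adj <- matrix(FALSE, n_ch, n_ch)
    for (a in 1:(n_ch - 1)) for (b in (a + 1):n_ch) {
      pa <- pos[((a - 1) * 20 + 1):(a * 20), ]
      pb <- pos[((b - 1) * 20 + 1):(b * 20), ]
      dmin <- Inf
      for (k in 1:20) {
        dd <- sweep(pb, 2, pa[k, ])
        dd <- dd - 9 * round(dd / 9)
        dmin <- min(dmin, sqrt(min(rowSums(dd^2))))
      }
      adj[a, b] <- dmin < 0.75
    }
    gr <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
    want <- igraph::components(gr)$membership
    # same partition up to relabelling
    expect_equal(length(unique(lab)), length(unique(want)))
    expect_true(all(tapply(want, lab, function(v) length(unique(v))) == 1))
  }
})

test_that("cluster labels are invariant to chain order and box translation", {
  set.seed(66)
  n_ch <- 8
  com <- cbind(runif(n_ch, 0, 9), runif(n_ch, 0, 9), runif(n_ch, 0, 9))
  pos <- com[rep(1:n_ch, each = 20), ] + matrix(rnorm(n_ch * 60, sd = 0.5),
                                                ncol = 3)
  st <- hp_state(pos, matrix(0, n_ch * 20, 3), rep("H", n_ch * 20),
                 rep(1:n_ch, each = 20), c(9, 9, 9))
  lab <- cluster_chains(st, 0.75)
  # rigid translation across the periodic boundary
  st_tr <- st
  st_tr$positions <- sweep(st$positions, 2, c(4.5, -3, 7), "+")
  expect_equal(cluster_chains(st_tr, 0.75), lab)
  # chain relabelling: reverse chain order
  perm <- rev(seq_len(n_ch))
  idx <- unlist(lapply(perm, function(c) ((c - 1) * 20 + 1):(c * 20)))
  st_pm <- hp_state(st$positions[idx, ], matrix(0, n_ch * 20, 3),
                    rep("H", n_ch * 20), rep(seq_len(n_ch), each = 20),
                    c(9, 9, 9))
  lab_pm <- cluster_chains(st_pm, 0.75)
  expect_true(all(tapply(lab[perm], lab_pm, function(v) length(unique(v))) == 1))
  expect_error(cluster_chains(st, 5), "geometry")
})

test_that("cluster-size probabilities are chain-weighted and sum to one", {
  set.seed(67)
  # compact droplet of 20 chains: every chain in one cluster of size 20
  com <- cbind(runif(20, 4, 5), runif(20, 4, 5), runif(20, 4, 5))
  pos <- com[rep(1:20, each = 20), ] + matrix(rnorm(1200, sd = 0.25), ncol = 3)
  tr <- fake_traj(array(rep(c(pos), 4), c(400, 3, 4)), c(12, 12, 12),
                  rep("H", 400), rep(1:20, each = 20))
  csd <- cluster_size_distribution(tr, equil_frac = 0)
  expect_equal(sum(csd$P), 1, tolerance = 1e-6)
  expect_equal(csd$N_c[which.max(csd$P)], 20)
  expect_equal(attr(csd, "largest_fraction"), 1)

  # insensitivity to the contact cutoff between 1.3 and 1.7 sigma
  csd_lo <- cluster_size_distribution(tr, cutoff = 1.3 * 0.5, equil_frac = 0)
  csd_hi <- cluster_size_distribution(tr, cutoff = 1.7 * 0.5, equil_frac = 0)
  all_sizes <- sort(unique(c(csd_lo$N_c, csd_hi$N_c)))
  p_of <- function(csd) {
    p <- setNames(numeric(length(all_sizes)), all_sizes)
    p[as.character(csd$N_c)] <- csd$P
    p
  }
  tvd <- sum(abs(p_of(csd_lo) - p_of(csd_hi))) / 2
  expect_lt(tvd, 0.1)
})
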