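#' Simulation state container
#'
#' An `hp_state` bundles particle positions (nm), velocities (nm/fs), monomer
#' types, chain membership and the orthorhombic periodic box. Coordinates are
#' stored unwrapped (chains never break across the boundary); the minimum
#' image convention is applied wherever distances are computed.
#'
#' @param positions n x 3 matrix, nm.
#' @param velocities n x 3 matrix, nm/fs.
#' @param types character vector of "H"/"P".
#' @param chain_ids integer vector of chain indices (1-based, contiguous runs).
#' @param box length-3 numeric, box edges in nm.
#' @param time simulation time, fs.
#' @param seed seed recorded for provenance.
#' @return An object of class `hp_state`.
#' @export
hp_state <- function(positions, velocities, types, chain_ids, box,
                     time = 0, seed = NA_integer_) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            nrow(positions) == length(types),
            length(chain_ids) == length(types), length(box) == 3)
  structure(list(positions = positions, velocities = velocities,
                 types = types, chain_ids = as.integer(chain_ids),
                 box = as.numeric(box), time = time, seed = seed),
            class = "hp_state")
}

#' @export
print.hp_state <- function(x, ...) {
  cat(sprintf("<hp_state> %d particles, %d chains, box %s nm, t=%g fs\n",
              nrow(x$positions), length(unique(x$chain_ids)),
              paste(signif(x$box, 4), collapse = " x "), x$time))
  invisible(x)
}

MASS_BEAD <- 100   # g/mol
FCON <- 4.184e-6   # (g nm^2/fs^2) per (kcal/mol)

maxwell_velocities <- function(n, kT, mass = MASS_BEAD, seed = NULL) {
  sd_v <- sqrt(kT * FCON / mass)
  with_seed(seed, matrix(stats::rnorm(3 * n, sd = sd_v), ncol = 3))
}

# Self-avoiding random walk: bond length r0, no nonbonded pair closer than
# min_sep. Restarts on dead ends.
saw_chain <- function(N, r0, min_sep, max_try = 200) {
  if (N == 1) return(matrix(0, 1, 3))
  for (attempt in 1:50) {
    pos <- matrix(0, N, 3)
    ok <- TRUE
    for (i in 2:N) {
      placed <- FALSE
      for (t in 1:max_try) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- pos[i - 1, ] + r0 * u
        if (i > 2) {
          d2 <- rowSums(sweep(pos[1:(i - 2), , drop = FALSE], 2, cand)^2)
          if (min(d2) < min_sep^2) next
        }
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  abort("packing error: self-avoiding chain construction failed.")
}

# Compact snake-path chain on a cubic sublattice (used for dense packings).
lattice_chain <- function(N, spacing = 0.42) {
  side <- ceiling(N^(1 / 3))
  while (side^3 < N) side <- side + 1
  pos <- matrix(0, N, 3)
  k <- 1
  for (z in 0:(side - 1)) {
    ys <- if (z %% 2 == 0) 0:(side - 1) else (side - 1):0
    for (y in ys) {
      xs <- if ((z * side + y) %% 2 == 0) 0:(side - 1) else (side - 1):0
      for (x in xs) {
        if (k > N) break
        pos[k, ] <- c(x, y, z) * spacing
        k <- k + 1
      }
    }
  }
  # centre on the cube midpoint (not the centroid) so random axis flips in
  # the packers cannot push a partially-filled top layer into a neighbour
  sweep(pos, 2, rep((side - 1) / 2 * spacing, 3))
}

#' Initial-configuration builders
#'
#' `build_single_chain()` places one self-avoiding chain at the box centre.
#' `build_two_chains()` places two copies of the sequence with their centres
#' of mass a distance `r_com` apart along x. `build_slab()` packs the chains
#' into a dense central slab with surface normals along z (the
#' direct-coexistence geometry). `build_cubic()` disperses chains on a grid
#' through a cubic box (the self-assembly geometry).
#'
#' All builders guarantee bond lengths within `r0 +/- 0.05` nm and no
#' nonbonded pair closer than `0.8 * sigma`, and draw Maxwell-Boltzmann
#' velocities at `temperature`.
#'
#' @param seq a one-row sequence tibble ([generate_sequence()]).
#' @param seqs a sequence tibble, one row per chain (rows recycled if fewer
#'   rows than `n_chains`).
#' @param box numeric length-3, nm.
#' @param r_com target centre-of-mass separation, nm.
#' @param n_chains number of chains to place.
#' @param edge cubic box edge, nm.
#' @param slab_conc target initial slab concentration, mg/mL. The default
#'   (500) is roughly 0.8 of the dense-phase concentration of the purely
#'   hydrophobic reference.
#' @param temperature K, for the initial velocities.
#' @param ff force field (for `sigma`, `r0`).
#' @param seed RNG seed.
#' @return An [hp_state()].
#' @export
build_single_chain <- function(seq, box = c(25, 25, 25),
                               ff = hp_forcefield("HP"), temperature = 300,
                               seed = NULL) {
  mono <- monomers_of(seq)
  N <- length(mono)
  pos <- with_seed(seed, saw_chain(N, ff$r0, 0.8 * ff$sigma))
  pos <- sweep(pos, 2, colMeans(pos)) +
    matrix(box / 2, N, 3, byrow = TRUE)
  vel <- maxwell_velocities(N, kT_at(temperature),
                            seed = if (is.null(seed)) NULL else derive_seed(seed, "vel"))
  hp_state(pos, vel, mono, rep(1L, N), box,
           seed = if (is.null(seed)) NA_integer_ else seed)
}

#' @rdname build_single_chain
#' @export
build_two_chains <- function(seq, r_com, box = c(25, 25, 25),
                             ff = hp_forcefield("HP"), temperature = 300,
                             seed = NULL) {
  mono <- monomers_of(seq)
  N <- length(mono)
  pos <- with_seed(seed, {
    for (t in 1:500) {
      a <- saw_chain(N, ff$r0, 0.8 * ff$sigma)
      b <- saw_chain(N, ff$r0, 0.8 * ff$sigma)
      a <- sweep(a, 2, colMeans(a))
      b <- sweep(b, 2, colMeans(b))
      b <- sweep(b, 2, c(r_com, 0, 0), "+")
      d2min <- min(as.matrix(stats::dist(rbind(a, b)))[1:N, (N + 1):(2 * N)])
      if (d2min >= 0.8 * ff$sigma) break
      if (t == 500) abort("packing error: could not place two chains without overlap.")
    }
    rbind(a, b)
  })
  pos <- sweep(pos, 2, colMeans(pos)) + matrix(box / 2, 2 * N, 3, byrow = TRUE)
  # exact COM separation along x after centring
  comA <- colMeans(pos[1:N, , drop = FALSE])
  comB <- colMeans(pos[(N + 1):(2 * N), , drop = FALSE])
  shift <- (r_com - (comB[1] - comA[1]))
  pos[(N + 1):(2 * N), 1] <- pos[(N + 1):(2 * N), 1] + shift
  pos[(N + 1):(2 * N), 2:3] <- sweep(pos[(N + 1):(2 * N), 2:3, drop = FALSE], 2,
                                     comB[2:3] - comA[2:3])
  vel <- maxwell_velocities(2 * N, kT_at(temperature),
                            seed = if (is.null(seed)) NULL else derive_seed(seed, "vel"))
  hp_state(pos, vel, rep(mono, 2), rep(1:2, each = N), box,
           seed = if (is.null(seed)) NA_integer_ else seed)
}

place_chain_grid <- function(seqs, n_chains, cells, origin, pitch, box,
                             temperature, seed) {
  rows <- rep(seq_len(nrow(seqs)), length.out = n_chains)
  conf <- lattice_chain(nchar(seqs$sequence[1]))
  N <- nrow(conf)
  pos <- matrix(0, n_chains * N, 3)
  types <- character(n_chains * N)
  with_seed(seed, {
    for (k in seq_len(n_chains)) {
      cell <- cells[k, ]
      centre <- origin + (cell - 0.5) * pitch
      # random axis permutation + flips decorrelate neighbouring chains
      perm <- sample(3)
      flip <- sample(c(-1, 1), 3, replace = TRUE)
      p <- conf[, perm, drop = FALSE]
      p <- sweep(p, 2, flip, "*")
      idx <- ((k - 1) * N + 1):(k * N)
      pos[idx, ] <- sweep(p, 2, centre, "+")
      types[idx] <- monomers_of(seqs[rows[k], ])
    }
  })
  vel <- maxwell_velocities(n_chains * N, kT_at(temperature),
                            seed = if (is.null(seed)) NULL else derive_seed(seed, "vel"))
  hp_state(pos, vel, types, rep(seq_len(n_chains), each = N), box,
           seed = if (is.null(seed)) NA_integer_ else seed)
}

#' @rdname build_single_chain
#' @export
build_slab <- function(seqs, n_chains = 100, box = c(10, 10, 40),
                       slab_conc = 500, temperature = 300, seed = NULL) {
  N <- nchar(seqs$sequence[1])
  mass_mg <- n_chains * N * MASS_BEAD / 6.02214076e20   # mg
  vol_ml <- mass_mg / slab_conc                          # mL
  thick <- vol_ml * 1e21 / (box[1] * box[2])             # nm
  thick <- min(thick, 0.9 * box[3])
  pitch_min <- 1.25
  nx <- max(1, floor(box[1] / pitch_min))
  ny <- max(1, floor(box[2] / pitch_min))
  nz <- max(1, ceiling(n_chains / (nx * ny)))
  if (nz * pitch_min > thick) thick <- nz * pitch_min
  pitch <- c(box[1] / nx, box[2] / ny, thick / nz)
  cells <- as.matrix(expand.grid(x = 1:nx, y = 1:ny, z = 1:nz))
  if (nrow(cells) < n_chains) abort("packing error: slab cannot hold the requested chains.")
  cells <- cells[seq_len(n_chains), , drop = FALSE]
  origin <- c(0, 0, (box[3] - thick) / 2)
  place_chain_grid(seqs, n_chains, cells, origin, pitch, box, temperature, seed)
}

#' @rdname build_single_chain
#' @export
build_cubic <- function(seqs, n_chains = 100, edge = 40, temperature = 300,
                        seed = NULL) {
  box <- rep(edge, 3)
  side <- ceiling(n_chains^(1 / 3))
  pitch <- rep(edge / side, 3)
  cells <- as.matrix(expand.grid(x = 1:side, y = 1:side, z = 1:side))
  cells <- cells[seq_len(n_chains), , drop = FALSE]
  place_chain_grid(seqs, n_chains, cells, c(0, 0, 0), pitch, box,
                   temperature, seed)
}

#' Langevin dynamics propagation
#'
#' Integrates the state under the force field with a BAOAB-discretized
#' Langevin scheme at fixed temperature. The low-friction defaults
#' (`gamma = 0.1` g/(mol fs), `dt = 10` fs, 300 K) are the production
#' conditions used throughout the package. With `gamma = 0` the scheme
#' degenerates to velocity Verlet (useful for energy-conservation checks).
#'
#' @param state an [hp_state()].
#' @param ff an [hp_forcefield()].
#' @param n_steps number of timesteps.
#' @param dt timestep, fs.
#' @param gamma friction coefficient, g/(mol fs).
#' @param temperature K.
#' @param sample_every store a frame every this many steps.
#' @param seed integer; the same (state, seed) pair reproduces the trajectory
#'   bit for bit.
#' @param bias optional umbrella bias on the chain-1/chain-2 centre-of-mass
#'   distance: `list(k = spring kcal/(mol nm^2), r0 = target nm)`. The
#'   centre-of-mass distance is then recorded every `rcom_every` steps.
#' @param rcom_every sampling stride for the biased COM distance.
#' @param skin neighbour-list skin, nm.
#' @return An `hp_trajectory`: frames (n x 3 x n_frames array of unwrapped
#'   positions), per-frame times (fs), nonbonded/bond potential and kinetic
#'   energies (kcal/mol), the final state, and the biased COM-distance series
#'   when a bias is active.
#' @export
run_langevin <- function(state, ff, n_steps, dt = 10, gamma = 0.1,
                         temperature = 300, sample_every = 1000, seed = 1,
                         bias = NULL, rcom_every = 10, skin = 0.4) {
  stopifnot(inherits(state, "hp_state"), n_steps >= 1)
  kT <- kT_at(temperature)
  bias_k <- if (is.null(bias)) 0 else bias$k
  bias_r0 <- if (is.null(bias)) 0 else bias$r0
  res <- cpp_run_langevin(state$positions, state$velocities,
                          type_index(state$types), state$chain_ids, state$box,
                          ff$epsilon, ff$sigma, ff$r_cut, ff$lambda_table,
                          ff$k_b, ff$r0,
                          as.integer(n_steps), dt, gamma, kT, MASS_BEAD,
                          as.integer(sample_every), as.double(seed),
                          bias_k, bias_r0, as.integer(rcom_every), skin)
  final <- hp_state(res$pos, res$vel, state$types, state$chain_ids,
                    state$box, time = state$time + n_steps * dt, seed = seed)
  structure(list(frames = res$frames, time = state$time + res$time,
                 u_nb = res$u_nb, u_bond = res$u_bond, ke = res$ke,
                 rcom = res$rcom, box = state$box, types = state$types,
                 chain_ids = state$chain_ids, dt = dt,
                 sample_every = sample_every, temperature = temperature,
                 seed = seed, final = final),
            class = "hp_trajectory")
}

#' @export
print.hp_trajectory <- function(x, ...) {
  cat(sprintf("<hp_trajectory> %d frames x %d particles, %g fs apart, box %s nm\n",
              n_frames(x), length(x$types), x$dt * x$sample_every,
              paste(signif(x$box, 4), collapse = " x ")))
  invisible(x)
}

#' Trajectory accessors
#' @param traj an `hp_trajectory`.
#' @param i frame index.
#' @return `n_frames()` the frame count; `frame_positions()` the n x 3
#'   position matrix of frame `i`; `kinetic_temperature()` the per-frame
#'   kinetic temperature series in K.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' @rdname n_frames
#' @export
frame_positions <- function(traj, i) traj$frames[, , i]

#' @rdname n_frames
#' @export
kinetic_temperature <- function(traj) {
  n <- length(traj$types)
  2 * traj$ke / (3 * n * KB_KCAL)
}

#' Neighbour pairs within a cutoff
#'
#' Minimum-image pair list built with a cell list; with a positive `skin`
#' the result is a superset of the pairs within `cutoff` (exactly the pairs
#' within `cutoff + skin`).
#'
#' @param state an [hp_state()].
#' @param cutoff nm.
#' @param skin nm.
#' @return Two-column integer matrix of particle index pairs (i < j).
#' @export
neighbor_pairs <- function(state, cutoff, skin = 0) {
  if (cutoff + skin >= min(state$box) / 2)
    abort("geometry error: cutoff + skin must be below half the smallest box edge.")
  cpp_neighbor_pairs(state$positions, state$box, cutoff + skin)
}

#' Extended-XYZ trajectory I/O
#'
#' Writes/reads frames as extended XYZ text: the comment line carries the
#' orthorhombic lattice, time and per-atom property spec; atom lines carry
#' monomer type, position (nm) and chain id.
#'
#' @param traj an `hp_trajectory`.
#' @param path file path.
#' @param every write every k-th frame.
#' @return `read_xyz()` returns a list with `frames`, `box`, `types`,
#'   `chain_ids`, `time`.
#' @export
write_xyz <- function(traj, path, every = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$types)
  for (i in seq(1, n_frames(traj), by = every)) {
    p <- frame_positions(traj, i)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:chain:I:1 Time=%g',
      traj$box[1], traj$box[2], traj$box[3], traj$time[i]), con)
    writeLines(sprintf("%s %.8g %.8g %.8g %d", traj$types,
                       p[, 1], p[, 2], p[, 3], traj$chain_ids), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- c(); box <- NULL; types <- NULL; chains <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]+"', hdr))
    lat_vals <- as.numeric(strsplit(sub('Lattice="', "", sub('"$', "", lat)), " ")[[1]])
    box <- lat_vals[c(1, 5, 9)]
    tm <- regmatches(hdr, regexpr("Time=\\S+", hdr))
    times <- c(times, if (length(tm)) as.numeric(sub("Time=", "", tm)) else NA)
    rows <- strsplit(lines[(i + 2):(i + 1 + n)], "\\s+")
    types <- vapply(rows, `[[`, "", 1)
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    chains <- as.integer(vapply(rows, `[[`, "", 5))
    frames[[length(frames) + 1]] <- pos
    i <- i + 2 + n
  }
  list(frames = frames, box = box, types = types, chain_ids = chains,
       time = times)
}
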