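# Shared fixtures built in code. Expensive objects (reference run,
# calibrations, slab campaigns) are computed once per test session and
# memoised here so the acceptance checks and the unit tests reuse them.

.hp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .hp_cache)) assign(key, force(expr), envir = .hp_cache)
  get(key, envir = .hp_cache)
}

# the 21-sequence composition grid used throughout the suite
test_seqs <- function() cached("seqs", sequence_grid(20, 0.05, seed = 42))

seq_at <- function(X_P) {
  s <- test_seqs()
  s[which.min(abs(s$X_P - X_P)), ]
}

# purely hydrophobic reference chain statistics
cached_reference <- function() {
  cached("reference", reference_rg("HP", n_steps = 2e6, seed = 11))
}

# Rg-matched scaling factor for one (model, X_P); short bisection campaign
cached_calibration <- function(model, X_P, n_steps = 3e5) {
  cached(paste0("cal_", model, "_", X_P),
         match_rg(seq_at(X_P), model, cached_reference(),
                  n_steps = n_steps, seed = 13))
}

# scaled-down direct-coexistence campaign (desk-scale variant of the
# 100-chain default geometry)
cached_slab <- function(model, X_P, lambda_H, n_steps = 15e4) {
  cached(paste0("slab_", model, "_", X_P, "_", signif(lambda_H, 6)), {
    ff <- hp_forcefield(model, lambda_H = lambda_H)
    coexistence_run(seq_at(X_P), ff, n_chains = 48, box = c(8, 8, 28),
                    n_steps = n_steps, sample_every = max(n_steps / 75, 2e3),
                    seed = 17, plateau_factor = 2)
  })
}

# dispersed-start self-assembly run in a compact cubic box; returns the
# cluster-size distribution after discarding the first half
cached_cubic <- function(model, X_P, lambda_H, n_steps = 2.5e5) {
  cached(paste0("cubic_", model, "_", X_P, "_", signif(lambda_H, 6)), {
    ff <- hp_forcefield(model, lambda_H = lambda_H)
    st <- build_cubic(seq_at(X_P), n_chains = 48, edge = 14, seed = 31)
    tr <- run_langevin(st, ff, n_steps = n_steps, sample_every = 5e3,
                       seed = 32)
    cluster_size_distribution(tr, equil_frac = 0.5)
  })
}

# fake minimal trajectory wrapper for analysis-only tests
fake_traj <- function(frames, box, types, chain_ids, dt = 10,
                      sample_every = 1000) {
  structure(list(frames = frames,
                 time = seq_len(dim(frames)[3]) * dt * sample_every,
                 u_nb = numeric(dim(frames)[3]),
                 u_bond = numeric(dim(frames)[3]),
                 ke = numeric(dim(frames)[3]),
                 box = box, types = types, chain_ids = as.integer(chain_ids),
                 dt = dt, sample_every = sample_every, temperature = 300,
                 seed = NA),
            class = "hp_trajectory")
}

# brute-force minimum-image nonbonded energy (oracle for the cell list)
brute_nb_energy <- function(state, ff) {
  pos <- state$positions
  n <- nrow(pos)
  lam <- ff$lambda_table
  u <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (state$chain_ids[i] == state$chain_ids[j] && abs(i - j) == 1) next
    d <- pos[i, ] - pos[j, ]
    d <- d - state$box * round(d / state$box)
    r <- sqrt(sum(d^2))
    if (r > ff$r_cut) next
    u <- u + pair_energy(r, lam[state$types[i], state$types[j]], ff)
  }
  u
}

# a single-bead "sequence" for degenerate two-body PMF checks
bead_seq <- function(type = "H") {
  tibble::tibble(label = paste0("bead", type), N = 1L, X_P = as.numeric(type == "P"),
                 n_P = as.integer(type == "P"), seed = NA_integer_,
                 patterned = FALSE, sequence = type)
}
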