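MG_PER_BEAD_NM3 <- 166.053907  # conc (mg/mL) = 166.05 * beads / volume(nm^3)

#' Concentration profile along the slab normal
#'
#' Time-averaged mass concentration binned along an axis (z by default).
#' With `center = TRUE` every frame is first re-centred on the periodic
#' (circular) centre of mass of the bead distribution along that axis, which
#' keeps a drifting slab's interfaces sharp in the average; bins are then
#' reported on `[-L/2, L/2)` around the slab midplane.
#'
#' @param traj an `hp_trajectory` from a slab run.
#' @param bin_width nm (must be at least half a bead diameter).
#' @param center re-centre frames on the periodic centre of mass.
#' @param equil_frac fraction of initial frames discarded.
#' @param axis 1, 2 or 3 (x, y, z).
#' @param n_blocks blocks for per-bin errors.
#' @return An `hp_profile`: tibble with `z` (bin centres, nm), `conc`
#'   (mg/mL), `se`; attributes carry the box, bin width and total
#'   concentration.
#' @export
density_profile <- function(traj, bin_width = 0.5, center = TRUE,
                            equil_frac = 0.1, axis = 3, n_blocks = 5) {
  nf <- n_frames(traj)
  if (nf < 1) abort("input error: empty trajectory.")
  use <- seq(floor(equil_frac * nf) + 1, nf)
  L <- traj$box[axis]
  areav <- prod(traj$box[-axis]) * bin_width
  nb <- max(1, round(L / bin_width))
  brks <- seq(-L / 2, L / 2, length.out = nb + 1)
  counts <- matrix(0, nb, length(use))
  for (j in seq_along(use)) {
    z <- traj$frames[, axis, use[j]]
    z <- z - L * floor(z / L)          # wrap into [0, L)
    if (center) {
      th <- 2 * pi * z / L
      zc <- (L / (2 * pi)) * atan2(mean(sin(th)), mean(cos(th)))
      z <- z - zc
    } else {
      z <- z - L / 2
    }
    z <- z - L * floor(z / L + 0.5)    # wrap into [-L/2, L/2)
    counts[, j] <- graphics::hist(z, breaks = brks, plot = FALSE)$counts
  }
  conc <- MG_PER_BEAD_NM3 * counts / areav
  bs <- length(use) %/% n_blocks
  bm <- vapply(seq_len(n_blocks), function(b)
    rowMeans(conc[, ((b - 1) * bs + 1):(b * bs), drop = FALSE]),
    numeric(nb))
  se <- apply(bm, 1, stats::sd) / sqrt(n_blocks)
  out <- tibble(z = (brks[-1] + brks[-(nb + 1)]) / 2,
                conc = rowMeans(conc), se = se)
  total <- MG_PER_BEAD_NM3 * length(traj$types) / prod(traj$box)
  structure(out, class = c("hp_profile", class(out)),
            box = traj$box, axis = axis, bin_width = bin_width,
            total_concentration = total, n_frames = length(use))
}

#' Coexistence concentrations from a slab profile
#'
#' Fits the symmetric interface form
#' \deqn{c(z) = \frac{c_d + c_l}{2} - \frac{c_d - c_l}{2}
#'   \tanh\!\left(\frac{|z| - z_0}{d}\right)}
#' to a centred slab profile, returning the dense/dilute plateau
#' concentrations, the interface position `z0` and width `d`.
#'
#' @param profile an `hp_profile`.
#' @return An `hp_coex` object; `tidy()` gives the parameter table,
#'   `glance()` a one-row summary.
#' @export
extract_coexistence <- function(profile) {
  df <- tibble(z = abs(profile$z), c = profile$conc)
  c_d0 <- mean(profile$conc[abs(profile$z) <= stats::quantile(abs(profile$z), 0.1)])
  c_l0 <- mean(profile$conc[abs(profile$z) >= stats::quantile(abs(profile$z), 0.85)])
  half <- (c_d0 + c_l0) / 2
  # starting interface position: where the folded profile crosses half-height
  agg <- stats::aggregate(c ~ z, data = df, FUN = mean)
  above <- agg$z[agg$c > half]
  below <- agg$z[agg$c < half]
  z00 <- if (length(above) && length(below) && max(above) < max(agg$z)) {
    (max(above) + min(below[below > max(above) - 1e-9])) / 2
  } else max(df$z) / 4
  if (!is.finite(z00)) z00 <- max(df$z) / 4
  do_fit <- function(d_lo, d_start) {
    try(minpack.lm::nlsLM(
      c ~ (cd + cl) / 2 - (cd - cl) / 2 * tanh((z - z0) / d), data = df,
      start = list(cd = c_d0, cl = max(c_l0, 1e-3), z0 = z00, d = d_start),
      lower = c(0, 0, 0, d_lo),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  }
  fit <- do_fit(1e-3, 1)
  if (inherits(fit, "try-error")) {
    # fall back to a resolution-limited interface width (half a bin)
    d_min <- max(1e-3, 0.5 * stats::median(diff(sort(unique(profile$z)))))
    fit <- do_fit(d_min, max(1, d_min))
  }
  if (inherits(fit, "try-error"))
    abort("classification error: interface fit failed to converge (no slab?).")
  p <- as.list(coef(fit))
  if (p$cd < p$cl)
    abort("classification error: fitted plateaus inverted (dense < dilute).")
  if ((p$cd - p$cl) < 0.05 * mean(profile$conc))
    abort("classification error: no interface (profile flat).")
  # plateau concentrations from bins at least 3 interface widths away from
  # the interface: unbiased by the fit's bounded width, lower variance than
  # the parametric values on noisy profiles
  dense_bins <- abs(profile$z) < p$z0 - 3 * p$d
  dilute_bins <- abs(profile$z) > p$z0 + 3 * p$d
  c_dense <- if (sum(dense_bins) >= 2) mean(profile$conc[dense_bins]) else p$cd
  c_dilute <- if (sum(dilute_bins) >= 2) mean(profile$conc[dilute_bins]) else p$cl
  structure(list(c_dense = c_dense, c_dilute = c_dilute, z0 = p$z0, d = p$d,
                 fit = fit, profile = profile),
            class = "hp_coex")
}

#' @export
print.hp_coex <- function(x, ...) {
  cat(sprintf("<hp_coex> c_dense = %.1f mg/mL, c_dilute = %.2f mg/mL, interface z0 = %.2f nm, width d = %.2f nm\n",
              x$c_dense, x$c_dilute, x$z0, x$d))
  invisible(x)
}

#' @rdname extract_coexistence
#' @param x an `hp_coex`.
#' @param ... unused.
#' @export
tidy.hp_coex <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @rdname extract_coexistence
#' @export
glance.hp_coex <- function(x, ...) {
  tibble(c_dense = x$c_dense, c_dilute = x$c_dilute, z0 = x$z0, d = x$d,
         plateau_width = 2 * x$z0, interface_width = x$d)
}

#' Classify a coexistence run as slab, cluster or homogeneous
#'
#' A run is a `slab` when the interface fit converges with a dense plateau at
#' least `plateau_factor` interface widths wide and the largest chain cluster
#' holds at least `largest_frac` of the chains; a `cluster` state has a
#' sub-threshold largest-cluster fraction together with substantial
#' probability mass at small cluster sizes; `homogeneous` means the profile
#' is flat within `flat_sigma` standard errors. Contradictory indicators
#' yield `"indeterminate"` (with a warning), not an error.
#'
#' @param profile an `hp_profile`.
#' @param csd an `hp_csd` from [cluster_size_distribution()] on the same run.
#' @param largest_frac slab threshold on the mean largest-cluster chain
#'   fraction (default 0.9).
#' @param plateau_factor minimum dense-plateau width in interface widths.
#' @param flat_sigma flatness tolerance in per-bin SEs.
#' @return A single string: `"slab"`, `"cluster"`, `"homogeneous"` or
#'   `"indeterminate"`.
#' @export
classify_phase_state <- function(profile, csd, largest_frac = 0.9,
                                 plateau_factor = 4, flat_sigma = 3) {
  lf <- attr(csd, "largest_fraction")
  flat <- all(abs(profile$conc - mean(profile$conc)) <=
                flat_sigma * pmax(profile$se, 1e-12))
  if (flat) return("homogeneous")
  cx <- try(extract_coexistence(profile), silent = TRUE)
  slab_profile <- !inherits(cx, "try-error") &&
    (2 * cx$z0) >= plateau_factor * cx$d &&
    cx$c_dense > 2 * cx$c_dilute
  if (slab_profile && lf >= largest_frac) return("slab")
  small_mass <- sum(csd$P[csd$N_c <= max(csd$N_c) / 2])
  if (lf < largest_frac && small_mass > 0.05) return("cluster")
  if (lf < largest_frac) return("cluster")
  warn("contradictory phase indicators; returning 'indeterminate'.")
  "indeterminate"
}

#' Radial distribution function between hydrophobic monomers
#'
#' Standard g(r) over H monomers, optionally restricted to a z-region (the
#' dense slab), normalized by the ideal-gas pair count at the region's H
#' density.
#'
#' @param traj an `hp_trajectory`.
#' @param dense_region optional `c(zmin, zmax)` in wrapped box coordinates
#'   (0..Lz); `NULL` uses the whole box.
#' @param dr bin width, nm.
#' @param r_max maximum distance, nm.
#' @param equil_frac fraction of initial frames discarded.
#' @return A tibble with `r`, `g`.
#' @export
rdf_HH <- function(traj, dense_region = NULL, dr = 0.02, r_max = 2.5,
                   equil_frac = 0.1) {
  nf <- n_frames(traj)
  use <- seq(floor(equil_frac * nf) + 1, nf)
  isH <- traj$types == "H"
  if (!any(isH)) abort("input error: no H monomers present.")
  brks <- seq(0, r_max, by = dr)
  nb <- length(brks) - 1
  counts <- numeric(nb); norm <- 0
  box <- traj$box
  for (j in use) {
    pos <- traj$frames[, , j]
    zw <- pos[, 3] - box[3] * floor(pos[, 3] / box[3])
    keep <- isH & (if (is.null(dense_region)) TRUE
                   else zw >= dense_region[1] & zw <= dense_region[2])
    p <- pos[keep, , drop = FALSE]
    nH <- nrow(p)
    if (nH < 2) next
    vol <- if (is.null(dense_region)) prod(box)
           else box[1] * box[2] * (dense_region[2] - dense_region[1])
    prs <- cpp_neighbor_pairs(p, box, r_max)
    if (nrow(prs) > 0) {
      dvec <- p[prs[, 1], , drop = FALSE] - p[prs[, 2], , drop = FALSE]
      dvec <- dvec - sweep(round(sweep(dvec, 2, box, "/")), 2, box, "*")
      d <- sqrt(rowSums(dvec^2))
      counts <- counts + graphics::hist(d[d < r_max], breaks = brks,
                                        plot = FALSE)$counts
    }
    rho <- nH / vol
    norm <- norm + nH * rho / 2
  }
  mids <- (brks[-1] + brks[-(nb + 1)]) / 2
  shell <- 4 * pi * mids^2 * dr
  tibble(r = mids, g = counts / (norm * shell))
}

#' Chain clustering by interchain contacts
#'
#' Two chains belong to the same cluster when any pair of their monomers is
#' within `cutoff` (default 1.5 sigma) under minimum image. Components are
#' found by union-find on the chain contact graph.
#'
#' @param state an [hp_state()] or a single frame extracted from a
#'   trajectory via [frame_state()].
#' @param cutoff contact distance, nm.
#' @return Integer vector of cluster labels, one per chain (labels are
#'   1..n_clusters in order of first appearance).
#' @export
cluster_chains <- function(state, cutoff = 0.75) {
  if (cutoff >= min(state$box) / 2)
    abort("geometry error: cutoff must be below half the smallest box edge.")
  chains <- sort(unique(state$chain_ids))
  n <- length(chains)
  edges <- cpp_contact_edges(state$positions, match(state$chain_ids, chains),
                             state$box, cutoff)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Extract one frame of a trajectory as an [hp_state()]
#' @param traj an `hp_trajectory`.
#' @param i frame index.
#' @return An `hp_state` (velocities zeroed).
#' @export
frame_state <- function(traj, i) {
  p <- frame_positions(traj, i)
  hp_state(p, matrix(0, nrow(p), 3), traj$types, traj$chain_ids, traj$box,
           time = traj$time[i])
}

#' Cluster-size distribution over a trajectory
#'
#' Probability that a chain resides in a cluster of size `N_c` (chain-
#' weighted, so `sum(P) = 1`), averaged over frames, with 5-block errors.
#' The attribute `largest_fraction` carries the mean fraction of chains in
#' the largest cluster, used by the phase classifier.
#'
#' @param traj an `hp_trajectory`.
#' @param cutoff contact distance, nm (default 1.5 sigma = 0.75 nm).
#' @param equil_frac fraction of initial frames discarded.
#' @param n_blocks blocks for errors.
#' @return An `hp_csd` tibble with `N_c`, `P`, `se`.
#' @export
cluster_size_distribution <- function(traj, cutoff = 0.75, equil_frac = 0.1,
                                      n_blocks = 5) {
  nf <- n_frames(traj)
  use <- seq(floor(equil_frac * nf) + 1, nf)
  n_chains <- length(unique(traj$chain_ids))
  Pmat <- matrix(0, n_chains, length(use))  # row = cluster size
  lfrac <- numeric(length(use))
  for (j in seq_along(use)) {
    lab <- cluster_chains(frame_state(traj, use[j]), cutoff)
    sizes <- tabulate(lab)
    lfrac[j] <- max(sizes) / n_chains
    for (s in sizes) Pmat[s, j] <- Pmat[s, j] + s / n_chains
  }
  keep <- which(rowSums(Pmat) > 0)
  bs <- length(use) %/% n_blocks
  se <- vapply(keep, function(s) {
    bm <- vapply(seq_len(n_blocks), function(b)
      mean(Pmat[s, ((b - 1) * bs + 1):(b * bs)]), numeric(1))
    stats::sd(bm) / sqrt(n_blocks)
  }, numeric(1))
  out <- tibble(N_c = keep, P = rowMeans(Pmat)[keep], se = se)
  structure(out, class = c("hp_csd", class(out)),
            largest_fraction = mean(lfrac), cutoff = cutoff,
            n_chains = n_chains)
}

#' Per-chain radius of gyration split by phase membership
#'
#' Chains in the largest cluster are counted as dense-phase, the rest as
#' dilute-phase; returns the mean single-chain Rg of each group.
#'
#' @param traj an `hp_trajectory`.
#' @param cutoff contact cutoff, nm.
#' @param equil_frac fraction of initial frames discarded.
#' @return A tibble with `phase`, `mean_Rg`, `n_chain_frames`.
#' @export
rg_by_phase <- function(traj, cutoff = 0.75, equil_frac = 0.1) {
  nf <- n_frames(traj)
  use <- seq(floor(equil_frac * nf) + 1, nf)
  chains <- sort(unique(traj$chain_ids))
  acc <- c(dense = 0, dilute = 0); cnt <- c(dense = 0, dilute = 0)
  for (j in use) {
    st <- frame_state(traj, j)
    lab <- cluster_chains(st, cutoff)
    big <- which.max(tabulate(lab))
    for (ci in seq_along(chains)) {
      p <- st$positions[traj$chain_ids == chains[ci], , drop = FALSE]
      grp <- if (lab[ci] == big) "dense" else "dilute"
      acc[grp] <- acc[grp] + radius_of_gyration(p)
      cnt[grp] <- cnt[grp] + 1
    }
  }
  tibble(phase = names(acc), mean_Rg = ifelse(cnt > 0, acc / cnt, NA_real_),
         n_chain_frames = as.integer(cnt))
}

#' Slab campaign for one sequence at one composition
#'
#' Builds the slab, runs Langevin dynamics, and returns the profile, the
#' cluster-size distribution, the phase classification, and (for slabs) the
#' coexistence concentrations — one `PhasePoint` row of the phase diagram.
#'
#' @param seq one-row sequence tibble.
#' @param ff force field (already calibrated).
#' @param n_chains chains in the slab.
#' @param box box edges, nm.
#' @param n_steps Langevin steps.
#' @param sample_every frame stride.
#' @param seed RNG seed.
#' @param bin_width profile bin width, nm.
#' @param plateau_factor passed to [classify_phase_state()]; desk-scale
#'   geometries (thin slabs, a few interface widths thick) need a smaller
#'   value than the default 4.
#' @return A list with `point` (one-row tibble: X_P, model, state, c_dilute,
#'   c_dense), `profile`, `csd`, `traj`.
#' @export
coexistence_run <- function(seq, ff, n_chains = 100, box = c(10, 10, 40),
                            n_steps = 2e6, sample_every = 5000, seed = 1,
                            bin_width = 0.5, plateau_factor = 4) {
  st <- build_slab(seq, n_chains = n_chains, box = box,
                   seed = derive_seed(seed, "slab"))
  tr <- run_langevin(st, ff, n_steps = n_steps, sample_every = sample_every,
                     seed = derive_seed(seed, "md"))
  prof <- density_profile(tr, bin_width = bin_width)
  csd <- cluster_size_distribution(tr)
  state <- classify_phase_state(prof, csd, plateau_factor = plateau_factor)
  cd <- NA_real_; cl <- NA_real_
  if (state == "slab") {
    cx <- extract_coexistence(prof)
    cd <- cx$c_dense; cl <- cx$c_dilute
  }
  point <- tibble(label = seq$label[[1]], X_P = seq$X_P[[1]],
                  model = ff$model, lambda_H = ff$lambda_H, state = state,
                  c_dilute = cl, c_dense = cd,
                  largest_fraction = attr(csd, "largest_fraction"))
  list(point = point, profile = prof, csd = csd, traj = tr)
}

#' Scan compositions for the phase-separation threshold
#'
#' Runs [coexistence_run()] over a composition grid with per-sequence
#' calibrated interaction strengths and reports the largest `X_P` classified
#' as a slab — the threshold `X_P*` at the grid's resolution.
#'
#' @param model `"HP"` or `"HP+"`.
#' @param calib_table tibble with columns `X_P` and `a` (or `lambda_H`);
#'   use `a = 1, lambda_H = 1` rows for the unscaled variant.
#' @param seqs sequence tibble (matched to `calib_table` by `X_P`).
#' @param ... passed to [coexistence_run()].
#' @param seed RNG seed.
#' @return A tibble of phase points with attribute `X_P_star` (NA when no
#'   composition forms a slab) and `resolution` (the grid spacing).
#' @export
threshold_scan <- function(model, calib_table, seqs, ..., seed = 1) {
  pts <- purrr::map_dfr(seq_len(nrow(calib_table)), function(i) {
    xp <- calib_table$X_P[i]
    row <- seqs[which.min(abs(seqs$X_P - xp)), ]
    lh <- if ("lambda_H" %in% names(calib_table)) calib_table$lambda_H[i]
          else scaled_lambda_H(calib_table$a[i], xp)
    ff <- hp_forcefield(model, lambda_H = lh)
    coexistence_run(row, ff, seed = derive_seed(seed, paste0("scan", i)),
                    ...)$point
  })
  slabs <- pts$X_P[pts$state == "slab"]
  xps <- sort(pts$X_P)
  res <- if (length(xps) > 1) min(diff(xps)) else NA_real_
  star <- if (length(slabs) > 0) max(slabs) else NA_real_
  if (length(slabs) == 0)
    warn("degenerate scan: no composition formed a slab.")
  structure(pts, X_P_star = star, resolution = res)
}
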