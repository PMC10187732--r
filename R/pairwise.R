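#' Two-chain potential of mean force by umbrella sampling
#'
#' Runs a ladder of Langevin simulations, each with a harmonic bias
#' `U = (k/2) (r - r_w)^2` on the centre-of-mass distance between the two
#' chains, walking the windows inward from the largest separation (each
#' window starts from the previous window's final state). The unbiased free
#' energy along `r` is recovered by the weighted-histogram method (WHAM)
#' iterated to a tolerance of 1e-8, and shifted so the mean over the outer
#' 10% of the grid is zero. Per-point errors come from 5-block WHAM
#' re-solves.
#'
#' @param seq one-row sequence tibble.
#' @param ff force field.
#' @param windows bias centres, nm (default 0.4 to 6 nm every 0.2 nm).
#' @param spring_k bias spring constant, kcal/(mol nm^2).
#' @param steps_per_window Langevin steps per window.
#' @param equil_frac fraction of each window's samples discarded.
#' @param bin_width histogram bin width, nm.
#' @param box cubic box edge, nm (must exceed `2 * max(windows)`).
#' @param seed RNG seed.
#' @param n_blocks blocks for the per-point error estimate.
#' @return An object of class `hp_pmf`: tibble-like list with `r`, `w`
#'   (kcal/mol), `se`, plus window diagnostics.
#' @export
umbrella_pmf <- function(seq, ff, windows = seq(0.4, 6, by = 0.2),
                         spring_k = 5, steps_per_window = 2e5,
                         equil_frac = 0.2, bin_width = 0.05,
                         box = NULL, seed = 1, n_blocks = 5) {
  windows <- sort(windows, decreasing = TRUE)
  kT <- kT_at(300)
  # histogram support must cover the outer windows' full sampled range
  sigma_w <- sqrt(kT / spring_k)
  if (is.null(box)) box <- rep(2 * (max(windows) + 3.5 * sigma_w) + 1, 3)
  st <- build_two_chains(seq, r_com = windows[1], box = box, ff = ff,
                         seed = derive_seed(seed, "b2"))
  samples <- vector("list", length(windows))
  for (wi in seq_along(windows)) {
    tr <- run_langevin(st, ff, n_steps = steps_per_window,
                       sample_every = steps_per_window,  # frames not needed
                       seed = derive_seed(seed, paste0("win", wi)),
                       bias = list(k = spring_k, r0 = windows[wi]),
                       rcom_every = 10)
    rs <- tr$rcom
    samples[[wi]] <- rs[-seq_len(floor(equil_frac * length(rs)))]
    st <- tr$final
  }
  grid <- seq(max(bin_width, min(windows) - 3.5 * sigma_w),
              max(windows) + 3.5 * sigma_w, by = bin_width)
  full <- wham_solve(samples, windows, spring_k, kT, grid)
  # coverage check: adjacent windows must produce overlapping histograms
  rngs <- t(vapply(samples, range, numeric(2)))
  ord <- order(windows)
  for (i in seq_len(length(windows) - 1)) {
    a <- ord[i]; b <- ord[i + 1]
    if (rngs[a, 2] < rngs[b, 1])
      abort(sprintf("coverage error: no histogram overlap between windows at %.2f and %.2f nm.",
                    windows[a], windows[b]))
  }
  # block errors: split each window's series into n_blocks, re-solve
  wblocks <- matrix(NA_real_, length(full$r), n_blocks)
  for (b in seq_len(n_blocks)) {
    sub <- lapply(samples, function(s) {
      bs <- length(s) %/% n_blocks
      s[((b - 1) * bs + 1):(b * bs)]
    })
    wblocks[, b] <- wham_solve(sub, windows, spring_k, kT, grid)$w
  }
  se <- apply(wblocks, 1, function(v) stats::sd(v[is.finite(v)]) /
                sqrt(sum(is.finite(v))))
  new_pmf(full$r, full$w, se, method = "umbrella",
          details = list(windows = windows, spring_k = spring_k,
                         n_samples = lengths(samples)))
}

# standard WHAM self-consistency on binned biased samples
wham_solve <- function(samples, centers, spring_k, kT, grid, tol = 1e-8,
                       max_iter = 5000) {
  nb <- length(grid) - 1
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  # samples outside the grid are dropped, not clamped: piling them into the
  # edge bins would distort the edge windows' free energies
  H <- vapply(samples, function(s)
    graphics::hist(s[s >= grid[1] & s <= grid[length(grid)]],
                   breaks = grid, plot = FALSE)$counts, numeric(nb))
  Ntot <- colSums(H)          # per-window totals
  Hsum <- rowSums(H)          # per-bin totals
  # bias energies: windows x bins
  Ub <- outer(seq_along(centers), seq_len(nb),
              function(i, j) 0.5 * spring_k * (mids[j] - centers[i])^2)
  f <- rep(0, length(centers))
  for (it in seq_len(max_iter)) {
    denom <- colSums(Ntot * exp((f - Ub) / kT))  # over windows, per bin
    P <- ifelse(denom > 0, Hsum / denom, 0)
    fnew <- -kT * log(pmax(exp(-Ub / kT) %*% P, 1e-300))[, 1]
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  P <- P / sum(P)
  # divide out the 4*pi*r^2 measure of the 3D separation vector so w(r) is
  # the pair PMF that decays to 0 at large r
  w <- ifelse(P > 0, -kT * (log(P) - 2 * log(mids)), Inf)
  # anchor the zero on the outer 15% of the grid, weighting bins by their
  # total counts so sparsely-visited edge bins cannot shift the whole curve
  tail_idx <- which(mids >= stats::quantile(mids, 0.85) & is.finite(w) &
                      Hsum > 0)
  w <- w - stats::weighted.mean(w[tail_idx], Hsum[tail_idx])
  list(r = mids, w = w)
}

new_pmf <- function(r, w, se, method, details = list()) {
  keep <- is.finite(w)
  structure(list(r = r[keep], w = w[keep], se = se[keep], method = method,
                 details = details),
            class = "hp_pmf")
}

#' @export
print.hp_pmf <- function(x, ...) {
  wmin <- min(x$w)
  cat(sprintf("<hp_pmf> (%s) %d points on [%.2f, %.2f] nm; min w = %.3f kcal/mol at r = %.2f nm\n",
              x$method, length(x$r), min(x$r), max(x$r), wmin, x$r[which.min(x$w)]))
  invisible(x)
}

#' @export
as_tibble.hp_pmf <- function(x, ...) tibble(r = x$r, w = x$w, se = x$se)

#' @export
tidy.hp_pmf <- function(x, ...) as_tibble.hp_pmf(x)

#' Rigid-conformation Mayer-sampling estimate of the two-chain PMF
#'
#' Independent cross-check for [umbrella_pmf()]: draws pairs of single-chain
#' conformations from an unbiased conformation pool, gives each a random
#' orientation, fixes the centre-of-mass distance at `r`, and estimates
#' \deqn{w(r) = -k_BT \ln \langle e^{-\Delta U / k_BT} \rangle,}
#' where \eqn{\Delta U} is the interchain energy. Exact for rigid bodies;
#' for flexible chains it neglects intrachain relaxation in the pair field,
#' which is a good approximation at this model's weak couplings.
#'
#' @param seq one-row sequence tibble.
#' @param ff force field.
#' @param r_grid centre-of-mass distances, nm.
#' @param n_samples conformation pairs per distance.
#' @param pool optional n x 3 x m array of pre-sampled chain conformations;
#'   generated from a fresh single-chain run when omitted.
#' @param pool_steps Langevin steps for the pool run.
#' @param seed RNG seed.
#' @param n_blocks blocks for the error estimate.
#' @return An `hp_pmf` with an `ess` (effective sample size) column in
#'   `details`.
#' @export
mayer_pmf <- function(seq, ff, r_grid = seq(0.4, 6, by = 0.1),
                      n_samples = 2000, pool = NULL, pool_steps = 1e6,
                      seed = 1, n_blocks = 5) {
  kT <- kT_at(300)
  if (is.null(pool)) {
    st <- build_single_chain(seq, ff = ff, seed = derive_seed(seed, "pool"))
    tr <- run_langevin(st, ff, n_steps = pool_steps, sample_every = 500,
                       seed = derive_seed(seed, "poolmd"))
    nf <- n_frames(tr)
    use <- seq(floor(0.1 * nf) + 1, nf)
    pool <- tr$frames[, , use, drop = FALSE]
  }
  m <- dim(pool)[3]
  tidx <- type_index(monomers_of(seq))
  # centre every pool conformation once
  for (k in seq_len(m)) {
    pc <- matrix(pool[, , k], ncol = 3)
    pool[, , k] <- sweep(pc, 2, colMeans(pc))
  }
  res <- with_seed(derive_seed(seed, "mayer"), {
    ia <- sample.int(m, n_samples, replace = TRUE)
    ib <- sample.int(m, n_samples, replace = TRUE)
    rotA <- lapply(seq_len(n_samples), function(i) random_rotation())
    rotB <- lapply(seq_len(n_samples), function(i) random_rotation())
    purrr::map(seq_along(r_grid), function(gi) {
      r <- r_grid[gi]
      bf <- vapply(seq_len(n_samples), function(s) {
        A <- matrix(pool[, , ia[s]], ncol = 3) %*% rotA[[s]]
        B <- sweep(matrix(pool[, , ib[s]], ncol = 3) %*% rotB[[s]], 2,
                   c(r, 0, 0), "+")
        du <- cpp_inter_energy(A, B, tidx, tidx, ff$epsilon, ff$sigma,
                               ff$r_cut, ff$lambda_table)
        exp(-du / kT)
      }, numeric(1))
      bf
    })
  })
  w <- vapply(res, function(bf) -kT * log(mean(bf)), numeric(1))
  ess <- vapply(res, function(bf) sum(bf)^2 / sum(bf^2), numeric(1))
  se <- vapply(res, function(bf) {
    bs <- length(bf) %/% n_blocks
    bm <- vapply(seq_len(n_blocks),
                 function(b) mean(bf[((b - 1) * bs + 1):(b * bs)]), numeric(1))
    if (any(bm <= 0)) return(Inf)
    stats::sd(-kT * log(bm)) / sqrt(n_blocks)
  }, numeric(1))
  if (all(!is.finite(w)))
    abort("sampling error: all Mayer samples are overlap-dominated.")
  new_pmf(r_grid, w, se, method = "mayer", details = list(ess = ess))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Second virial coefficient from a PMF
#'
#' \deqn{B_{22} = -2\pi \int_0^{r_{max}} \left[e^{-w(r)/k_BT} - 1\right] r^2
#'   \, dr} by trapezoidal quadrature; the region below the smallest sampled
#' distance is treated as a hard core (integrand `-r^2`). Negative values
#' indicate net chain-chain attraction, positive net repulsion.
#'
#' @param pmf an `hp_pmf` (or list with `r`, `w`, `se`).
#' @param temperature K.
#' @param tail_tol error if `|w|` at the largest distance exceeds this
#'   (kcal/mol): the integral has not converged.
#' @return A one-row tibble with `B22` (nm^3), `se`, `r_max`.
#' @export
b22 <- function(pmf, temperature = 300, tail_tol = 0.05) {
  kT <- kT_at(temperature)
  r <- pmf$r; w <- pmf$w
  o <- order(r); r <- r[o]; w <- w[o]
  se <- if (!is.null(pmf$se)) pmf$se[o] else rep(0, length(r))
  if (abs(w[length(w)]) > tail_tol)
    abort(sprintf("unconverged tail: |w(r_max)| = %.3f kcal/mol > %.3f.",
                  abs(w[length(w)]), tail_tol))
  mayer <- exp(-w / kT) - 1
  core <- 2 * pi / 3 * r[1]^3          # hard core below first sampled point
  integ <- -2 * pi * trapz(r, mayer * r^2)
  # SE propagation: dB/dw_i = 2*pi/kT * exp(-w_i/kT) * r_i^2 * (trapezoid wt)
  wts <- trapz_weights(r)
  dB <- 2 * pi / kT * exp(-w / kT) * r^2 * wts
  se_b <- sqrt(sum((dB * se)^2, na.rm = TRUE))
  tibble(B22 = core + integ, se = se_b, r_max = r[length(r)])
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}
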