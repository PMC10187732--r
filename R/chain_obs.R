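#' Gyration tensor, radius of gyration and shape anisotropy
#'
#' `gyration_tensor()` returns the 3x3 mass-weighted (equal masses) gyration
#' tensor of a set of unwrapped coordinates; `radius_of_gyration()` its trace
#' square root; `shape_anisotropy()` the eigenvalue invariant
#' \deqn{\kappa^2 = 1 - 3\,(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
#'   \lambda_3\lambda_1) / (\lambda_1+\lambda_2+\lambda_3)^2,}
#' which is 0 for spherical symmetry and 1 for a rod.
#'
#' @param coords n x 3 matrix of unwrapped chain coordinates, nm.
#' @return `gyration_tensor()`: symmetric 3x3 matrix (nm^2);
#'   `radius_of_gyration()`: nm; `shape_anisotropy()`: dimensionless in
#'   `[0, 1]`.
#' @export
gyration_tensor <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) >= 2)
  centred <- sweep(coords, 2, colMeans(coords))
  crossprod(centred) / nrow(coords)
}

#' @rdname gyration_tensor
#' @export
radius_of_gyration <- function(coords) {
  sqrt(sum(diag(gyration_tensor(coords))))
}

#' @rdname gyration_tensor
#' @param eigenvalues optionally, the three gyration-tensor eigenvalues
#'   (non-negative, not all zero) instead of `coords`.
#' @export
shape_anisotropy <- function(coords = NULL, eigenvalues = NULL) {
  if (is.null(eigenvalues)) {
    eigenvalues <- eigen(gyration_tensor(coords), symmetric = TRUE,
                         only.values = TRUE)$values
  }
  ev <- sort(pmax(eigenvalues, 0), decreasing = TRUE)
  s <- sum(ev)
  if (s <= 0) abort("undefined shape: all gyration-tensor eigenvalues are zero.")
  1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / s^2
}

# unwrapped coordinates of one chain in one frame, with a broken-chain guard
chain_coords <- function(traj, frame, chain = 1) {
  idx <- which(traj$chain_ids == chain)
  p <- traj$frames[idx, , frame, drop = FALSE]
  dim(p) <- c(length(idx), 3)
  bl <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(bl > min(traj$box) / 4))
    abort("coordinate error: chain appears wrapped/broken (bond > box/4); analyse unwrapped frames.")
  p
}

#' Block averaging error estimate
#'
#' Splits a series into `n_blocks` contiguous, equal-sized blocks (any
#' remainder is dropped from the front) and reports the mean and the standard
#' error of the block means, the package-wide convention for error bars on
#' time averages.
#'
#' @param series numeric vector.
#' @param n_blocks number of blocks (default 5).
#' @return A list with `mean`, `se`, `block_means`.
#' @export
block_error <- function(series, n_blocks = 5) {
  n <- length(series)
  if (n < n_blocks) abort("series shorter than the number of blocks.")
  bs <- n %/% n_blocks
  series <- series[(n - bs * n_blocks + 1):n]
  bm <- vapply(seq_len(n_blocks),
               function(b) mean(series[((b - 1) * bs + 1):(b * bs)]),
               numeric(1))
  list(mean = mean(bm), se = stats::sd(bm) / sqrt(n_blocks), block_means = bm)
}

#' End-to-end vector relaxation time
#'
#' Computes the normalized autocorrelation function of the chain end-to-end
#' vector and fits a stretched exponential
#' \eqn{C(t) = \exp[-(t/\tau_0)^\beta]}; the relaxation time is the ACF
#' integral \eqn{\tau_e = (\tau_0/\beta)\,\Gamma(1/\beta)}.
#'
#' @param traj an `hp_trajectory`, or `ee` an n_frames x 3 matrix of
#'   end-to-end vectors with `dt_frame` their spacing in fs.
#' @param ee,dt_frame see above; extracted from `traj` when omitted.
#' @param chain chain index.
#' @param fit_floor fit the ACF down to this value (default 0.05).
#' @return A list with `tau_e` (ns), `tau0` (ns), `beta`, and the ACF tibble
#'   used in the fit.
#' @export
end_to_end_relaxation <- function(traj = NULL, ee = NULL, dt_frame = NULL,
                                  chain = 1, fit_floor = 0.05) {
  if (is.null(ee)) {
    idx <- which(traj$chain_ids == chain)
    first <- idx[1]; last <- idx[length(idx)]
    ee <- t(traj$frames[last, , ] - traj$frames[first, , ])
    dt_frame <- traj$dt * traj$sample_every
  }
  if (stats::var(c(ee)) < 1e-12)
    abort("insufficient sampling: end-to-end vector does not fluctuate.")
  nlag <- min(nrow(ee) - 1, 5000)
  acfs <- vapply(1:3, function(k) {
    stats::acf(ee[, k], lag.max = nlag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(nlag + 1))
  w <- apply(ee, 2, stats::var)
  cf <- as.vector(acfs %*% w / sum(w))
  t_ns <- (seq_along(cf) - 1) * dt_frame * 1e-6
  below <- which(cf < exp(-1))
  if (length(below) == 0)
    abort("insufficient sampling: ACF never decays below 1/e within the trajectory.")
  keep <- seq_len(max(which(cf > fit_floor)[1], below[1]))
  keep <- keep[cf[keep] > 0]
  df <- tibble(t = t_ns[keep], c = cf[keep])
  tau_guess <- t_ns[below[1]]
  fit <- minpack.lm::nlsLM(c ~ exp(-(t / tau0)^beta), data = df,
                           start = list(tau0 = tau_guess, beta = 1),
                           lower = c(1e-9, 0.2), upper = c(Inf, 2),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  tau0 <- coef(fit)[["tau0"]]; beta <- coef(fit)[["beta"]]
  list(tau_e = (tau0 / beta) * gamma(1 / beta), tau0 = tau0, beta = beta,
       acf = df)
}

#' Intrachain distance scaling exponent
#'
#' Fits \eqn{\log \sqrt{\langle R^2(s) \rangle}} against \eqn{\log s} for
#' sequence separations `s = |i - j|` in `fit_range` (default `[3, N-1]`,
#' excluding bond-scale stiffness), giving the effective Flory exponent
#' \eqn{\nu} of the chain (0.5 for an ideal walk, ~0.588 for excluded-volume,
#' 1 for a rod).
#'
#' @param traj an `hp_trajectory` (single chain), or `msd_s` a precomputed
#'   named vector of mean squared internal distances by separation.
#' @param msd_s optional precomputed `<R^2(s)>`, names = separations.
#' @param chain chain index.
#' @param fit_range integer range of separations used in the fit.
#' @return A list with `nu`, `se`, and the per-separation tibble.
#' @export
intrachain_scaling <- function(traj = NULL, msd_s = NULL, chain = 1,
                               fit_range = NULL) {
  if (is.null(msd_s)) {
    idx <- which(traj$chain_ids == chain)
    N <- length(idx)
    acc <- numeric(N - 1); cnt <- numeric(N - 1)
    for (f in seq_len(n_frames(traj))) {
      p <- chain_coords(traj, f, chain)
      d2 <- as.matrix(stats::dist(p))^2
      for (s in 1:(N - 1)) {
        v <- d2[cbind(1:(N - s), (1 + s):N)]
        acc[s] <- acc[s] + sum(v)
        cnt[s] <- cnt[s] + length(v)
      }
    }
    msd_s <- setNames(acc / cnt, 1:(N - 1))
  }
  s <- as.numeric(names(msd_s))
  if (is.null(fit_range)) fit_range <- c(3, max(s))
  keep <- s >= fit_range[1] & s <= fit_range[2]
  if (sum(keep) < 4) abort("fit error: fewer than 4 separations in the fit range.")
  fit <- stats::lm(y ~ x, data = data.frame(x = log(s[keep]),
                                            y = 0.5 * log(msd_s[keep])))
  list(nu = unname(coef(fit)[2]),
       se = unname(summary(fit)$coefficients[2, 2]),
       data = tibble(s = s, rms = sqrt(msd_s)))
}

#' Single-chain ensemble statistics
#'
#' Per-frame radius of gyration, shape anisotropy and nonbonded energy are
#' averaged with 5-block standard errors; the gyration-radius histogram uses
#' Scott-rule bins and integrates to 1. Optionally adds the end-to-end
#' relaxation time and the intrachain scaling exponent.
#'
#' @param traj a single-chain `hp_trajectory`.
#' @param chain chain index.
#' @param n_blocks blocks for error estimation.
#' @param equil_frac fraction of initial frames discarded as equilibration.
#' @param dynamics also compute `tau_e` and `nu` (slower).
#' @return An object of class `hp_chain_stats`; see [glance.hp_chain_stats()].
#' @export
chain_ensemble_stats <- function(traj, chain = 1, n_blocks = 5,
                                 equil_frac = 0.1, dynamics = FALSE) {
  nf <- n_frames(traj)
  use <- seq(floor(equil_frac * nf) + 1, nf)
  rg <- numeric(length(use)); k2 <- numeric(length(use))
  for (j in seq_along(use)) {
    p <- chain_coords(traj, use[j], chain)
    gt <- gyration_tensor(p)
    rg[j] <- sqrt(sum(diag(gt)))
    k2[j] <- shape_anisotropy(eigenvalues = eigen(gt, symmetric = TRUE,
                                                  only.values = TRUE)$values)
  }
  brg <- block_error(rg, n_blocks)
  bk2 <- block_error(k2, n_blocks)
  bun <- block_error(traj$u_nb[use], n_blocks)
  h <- graphics::hist(rg, breaks = "Scott", plot = FALSE)
  hist_tbl <- tibble(Rg = h$mids, density = h$density)
  out <- list(mean_Rg = brg$mean, se_Rg = brg$se,
              kappa2 = bk2$mean, se_kappa2 = bk2$se,
              U_nb = bun$mean, se_U_nb = bun$se,
              Rg_histogram = hist_tbl, Rg_series = rg,
              n_blocks = n_blocks, n_frames_used = length(use),
              tau_e = NA_real_, beta = NA_real_, nu = NA_real_,
              se_nu = NA_real_)
  if (dynamics) {
    te <- try(end_to_end_relaxation(traj, chain = chain), silent = TRUE)
    if (!inherits(te, "try-error")) {
      out$tau_e <- te$tau_e
      out$beta <- te$beta
    }
    sc <- intrachain_scaling(traj, chain = chain)
    out$nu <- sc$nu
    out$se_nu <- sc$se
  }
  structure(out, class = "hp_chain_stats")
}

#' @export
print.hp_chain_stats <- function(x, ...) {
  cat(sprintf("<hp_chain_stats> <Rg> = %.4f +/- %.4f nm | <kappa^2> = %.3f +/- %.3f | U_nb = %.3f kcal/mol\n",
              x$mean_Rg, x$se_Rg, x$kappa2, x$se_kappa2, x$U_nb))
  if (!is.na(x$tau_e)) cat(sprintf("  tau_e = %.3g ns (beta %.2f)", x$tau_e, x$beta))
  if (!is.na(x$nu)) cat(sprintf("  nu = %.3f +/- %.3f", x$nu, x$se_nu))
  if (!is.na(x$tau_e) || !is.na(x$nu)) cat("\n")
  invisible(x)
}

#' One-row summary of chain ensemble statistics
#' @param x an `hp_chain_stats`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.hp_chain_stats <- function(x, ...) {
  tibble(mean_Rg = x$mean_Rg, se_Rg = x$se_Rg, kappa2 = x$kappa2,
         se_kappa2 = x$se_kappa2, U_nb = x$U_nb, se_U_nb = x$se_U_nb,
         tau_e = x$tau_e, nu = x$nu, se_nu = x$se_nu,
         n_frames = x$n_frames_used)
}

#' Bhattacharyya overlap between two gyration-radius distributions
#'
#' Histograms both samples on a common grid and returns
#' \eqn{\sum_k \sqrt{p_k q_k}} (1 = identical distributions).
#'
#' @param rg1,rg2 numeric samples.
#' @param n_bins number of common bins.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
rg_overlap <- function(rg1, rg2, n_bins = 40) {
  rng <- range(c(rg1, rg2))
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  p <- graphics::hist(rg1, breaks = brk, plot = FALSE)$counts
  q <- graphics::hist(rg2, breaks = brk, plot = FALSE)$counts
  sum(sqrt((p / sum(p)) * (q / sum(q))))
}
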