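#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

# one single-chain run -> mean Rg with block SE
rg_of_run <- function(seq, ff, n_steps, seed, sample_every = 500,
                      equil_frac = 0.1, box = c(25, 25, 25)) {
  st <- build_single_chain(seq, box = box, ff = ff,
                           seed = derive_seed(seed, "build"))
  tr <- run_langevin(st, ff, n_steps = n_steps, sample_every = sample_every,
                     seed = derive_seed(seed, "md"))
  nf <- n_frames(tr)
  use <- seq(floor(equil_frac * nf) + 1, nf)
  rg <- vapply(use, function(f) radius_of_gyration(chain_coords(tr, f)),
               numeric(1))
  be <- block_error(rg, 5)
  list(mean = be$mean, se = be$se)
}

#' Reference radius of gyration of the hydrophobic homopolymer
#'
#' Runs the purely hydrophobic chain (`X_P = 0`, `lambda_H = 1`) and returns
#' its mean single-chain radius of gyration with a 5-block standard error.
#' This is the target every other sequence/model is calibrated against.
#'
#' @param model `"HP"` or `"HP+"` (identical at `X_P = 0`; kept for
#'   bookkeeping).
#' @param N chain length.
#' @param n_steps Langevin steps for the run.
#' @param seed RNG seed.
#' @param max_rel_se sampling-quality gate: error if the block SE exceeds
#'   this fraction of the mean.
#' @return A list with `mean` (nm), `se` (nm), `model`, `N`.
#' @export
reference_rg <- function(model = "HP", N = 20, n_steps = 2e6, seed = 1,
                         max_rel_se = 0.02) {
  seq <- generate_sequence(N, 0, seed = seed)
  ff <- hp_forcefield(model, lambda_H = 1)
  r <- rg_of_run(seq, ff, n_steps, seed)
  if (r$se > max_rel_se * r$mean)
    abort(sprintf("sampling error: reference Rg block SE %.3g exceeds %.1f%% of the mean; lengthen the run.",
                  r$se, 100 * max_rel_se))
  list(mean = r$mean, se = r$se, model = model, N = N)
}

#' Calibrate the interaction scaling factor against the reference chain
#'
#' Finds the scaling factor `a` (with `lambda_H = a / (1 - X_P)`) such that
#' the sequence's single-chain mean radius of gyration matches the purely
#' hydrophobic reference. `<Rg>(a)` is monotone non-increasing, so the search
#' brackets a sign change of `f(a) = <Rg>(a) - reference` on a geometric grid
#' and bisects; it stops when `|f|` falls within `tolerance * reference` or
#' when the stochastic error dominates (`SE > |f|`), whichever comes first.
#'
#' @param seq one-row sequence tibble.
#' @param model `"HP"` or `"HP+"`.
#' @param reference result of [reference_rg()] (or a list with `mean`, `se`).
#' @param tolerance relative matching tolerance (default 0.03, the match
#'   quality achievable for the localized model away from extreme
#'   compositions).
#' @param a_bracket search interval for `a`.
#' @param n_steps Langevin steps per evaluation.
#' @param max_iter bisection iteration cap.
#' @param seed RNG seed.
#' @return An object of class `hp_calibration`; `tidy()` returns the
#'   evaluation trace, `glance()` a one-row summary.
#' @export
match_rg <- function(seq, model, reference, tolerance = 0.03,
                     a_bracket = c(0.1, 20), n_steps = 5e5, max_iter = 12,
                     seed = 1) {
  X_P <- seq$X_P[[1]]
  if (X_P >= 1) abort("cannot calibrate a purely polar chain (X_P = 1): no H monomers.")
  trace <- tibble(a = numeric(), Rg = numeric(), se = numeric())
  k <- 0
  fev <- function(a) {
    k <<- k + 1
    ff <- hp_forcefield(model, lambda_H = scaled_lambda_H(a, X_P))
    r <- rg_of_run(seq, ff, n_steps, derive_seed(seed, paste0("cal", k)))
    trace <<- bind_rows(trace, tibble(a = a, Rg = r$mean, se = r$se))
    r
  }
  target <- reference$mean

  # geometric grid until f(a) brackets zero (Rg decreases with a)
  grid <- sort(unique(c(1, exp(seq(log(a_bracket[1]), log(a_bracket[2]),
                                   length.out = 9)))))
  lo <- NA; hi <- NA; flo <- NA; fhi <- NA
  r1 <- fev(1)
  f1 <- r1$mean - target
  done <- abs(f1) <= tolerance * target || r1$se > abs(f1)
  best <- list(a = 1, Rg = r1$mean, se = r1$se)
  if (!done) {
    if (f1 > 0) { lo <- 1; flo <- f1; cand <- grid[grid > 1] }
    else        { hi <- 1; fhi <- f1; cand <- rev(grid[grid < 1]) }
    for (a in cand) {
      r <- fev(a)
      f <- r$mean - target
      if (abs(f) <= tolerance * target || r$se > abs(f)) {
        best <- list(a = a, Rg = r$mean, se = r$se); done <- TRUE; break
      }
      if (f > 0) { lo <- a; flo <- f } else { hi <- a; fhi <- f }
      if (!is.na(lo) && !is.na(hi)) break
    }
    if (!done && (is.na(lo) || is.na(hi)))
      abort(sprintf("calibration failure: no bracket for a in [%g, %g] (X_P = %g, %s model).",
                    a_bracket[1], a_bracket[2], X_P, model))
    it <- 0
    while (!done && it < max_iter) {
      it <- it + 1
      a <- sqrt(lo * hi)
      r <- fev(a)
      f <- r$mean - target
      best <- list(a = a, Rg = r$mean, se = r$se)
      if (abs(f) <= tolerance * target || r$se > abs(f)) { done <- TRUE; break }
      if (f > 0) { lo <- a } else { hi <- a }
    }
    if (!done) best <- list(a = sqrt(lo * hi), Rg = best$Rg, se = best$se)
  }
  # monotonicity check over the trace (within noise)
  tr_ord <- trace[order(trace$a), ]
  mono_viol <- any(diff(tr_ord$Rg) > 2 * (tr_ord$se[-1] + tr_ord$se[-nrow(tr_ord)]))
  structure(list(
    a = best$a, lambda_H = scaled_lambda_H(best$a, X_P),
    achieved_Rg = best$Rg, achieved_se = best$se,
    reference_Rg = reference$mean, reference_se = reference$se,
    rel_dev = abs(best$Rg - target) / target,
    converged = done, monotone = !mono_viol,
    model = model, X_P = X_P, label = seq$label[[1]],
    evaluations = trace
  ), class = "hp_calibration")
}

#' @export
print.hp_calibration <- function(x, ...) {
  cat(sprintf("<hp_calibration> %s model, X_P = %.2f: a = %.4f (lambda_H = %.4f)\n",
              x$model, x$X_P, x$a, x$lambda_H))
  cat(sprintf("  <Rg> = %.4f +/- %.4f nm vs reference %.4f +/- %.4f (|dev| = %.2f%%, %s)\n",
              x$achieved_Rg, x$achieved_se, x$reference_Rg, x$reference_se,
              100 * x$rel_dev, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @rdname match_rg
#' @param x an `hp_calibration`.
#' @param ... unused.
#' @export
tidy.hp_calibration <- function(x, ...) x$evaluations

#' @rdname match_rg
#' @export
glance.hp_calibration <- function(x, ...) {
  tibble(model = x$model, X_P = x$X_P, label = x$label, a = x$a,
         lambda_H = x$lambda_H, achieved_Rg = x$achieved_Rg,
         achieved_se = x$achieved_se, reference_Rg = x$reference_Rg,
         rel_dev = x$rel_dev, converged = x$converged,
         n_evaluations = nrow(x$evaluations))
}

#' Calibrate a whole sequence set
#'
#' Maps [match_rg()] over the rows of a sequence tibble (skipping `X_P = 1`)
#' and returns a tidy calibration table consumed by the coexistence, virial
#' and clustering stages.
#'
#' @param seqs sequence tibble.
#' @param model `"HP"` or `"HP+"`.
#' @param reference result of [reference_rg()].
#' @param ... passed to [match_rg()].
#' @return A tibble with one row per calibrated sequence.
#' @export
calibrate_sequences <- function(seqs, model, reference, ...) {
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    if (seqs$X_P[i] >= 1) return(NULL)
    glance(match_rg(seqs[i, ], model, reference, ...))
  })
}
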