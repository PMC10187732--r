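#' Construct a two-letter heteropolymer force field
#'
#' Builds the bonded + nonbonded parameter set for the hydrophobic/polar (H/P)
#' bead-spring model. Nonbonded interactions follow the Ashbaugh--Hatch
#' construction: the attractive tail of a Lennard-Jones potential is scaled by
#' a pairwise hydropathy \eqn{\lambda_{ij}} while the short-range repulsion is
#' kept intact, so \eqn{\lambda = 0} reduces exactly to the purely repulsive
#' WCA potential and \eqn{\lambda = 1} to the full Lennard-Jones form.
#'
#' Two mixing rules are supported. The `"HP"` model has strong localized
#' attraction between H monomers only (\eqn{\lambda_{HP} = 0}); the `"HP+"`
#' model adds weak distributed cross-attraction
#' \eqn{\lambda_{HP} = \lambda_H / 2}. Polar pairs never attract
#' (\eqn{\lambda_{PP} = 0}).
#'
#' @param model `"HP"` or `"HP+"`.
#' @param lambda_H hydropathy of the H monomer, dimensionless, `>= 0`.
#' @param epsilon Lennard-Jones well depth, kcal/mol.
#' @param sigma monomer diameter, nm.
#' @param k_b bond spring constant, kcal/(mol nm^2); bond energy is
#'   `k_b * (r - r0)^2` (prefactor absorbed in `k_b`).
#' @param r0 equilibrium bond length, nm.
#' @param r_cut nonbonded cutoff, nm (unshifted truncation).
#'
#' @return An object of class `hp_forcefield`: a list with the parameters and
#'   the symmetric 2x2 `lambda_table` (rows/cols H, P).
#' @examples
#' ff <- hp_forcefield("HP+", lambda_H = 1)
#' ff$lambda_table
#' @export
hp_forcefield <- function(model = c("HP", "HP+"), lambda_H = 1,
                          epsilon = 0.2, sigma = 0.5,
                          k_b = 2000, r0 = 0.38, r_cut = 4 * sigma) {
  model <- match.arg(model)
  if (!is.numeric(lambda_H) || length(lambda_H) != 1 || lambda_H < 0)
    abort("`lambda_H` must be a single non-negative number.")
  if (r_cut <= 2^(1 / 6) * sigma)
    abort("`r_cut` must exceed the potential minimum 2^(1/6)*sigma.")
  lambda_HP <- if (model == "HP+") lambda_H / 2 else 0
  tab <- matrix(c(lambda_H, lambda_HP, lambda_HP, 0), 2, 2,
                dimnames = list(c("H", "P"), c("H", "P")))
  structure(
    list(model = model, lambda_H = lambda_H, epsilon = epsilon, sigma = sigma,
         k_b = k_b, r0 = r0, r_cut = r_cut, lambda_table = tab),
    class = "hp_forcefield"
  )
}

#' @export
print.hp_forcefield <- function(x, ...) {
  cat(sprintf("<hp_forcefield> model=%s  eps=%g kcal/mol  sigma=%g nm  r_cut=%g nm\n",
              x$model, x$epsilon, x$sigma, x$r_cut))
  cat(sprintf("  bonds: U = k_b (r - r0)^2, k_b=%g kcal/(mol nm^2), r0=%g nm\n",
              x$k_b, x$r0))
  cat("  lambda table:\n")
  print(round(x$lambda_table, 6))
  invisible(x)
}

#' Hydropathy rescaling that compensates sequence composition
#'
#' Returns the H-monomer hydropathy \eqn{\lambda_H = a / (1 - X_P)} used to
#' tune attraction strength as the fraction of polar monomers grows. `a = 1`
#' keeps the sequence-average hydropathy equal to that of the purely
#' hydrophobic homopolymer; the calibration stage adjusts `a` so the
#' single-chain radius of gyration matches the homopolymer reference instead.
#'
#' @param a scaling factor, dimensionless.
#' @param X_P fraction of polar monomers, in `[0, 1)`.
#' @return `a / (1 - X_P)`, vectorized over both arguments.
#' @export
scaled_lambda_H <- function(a, X_P) {
  if (any(X_P < 0 | X_P >= 1))
    abort("`X_P` must lie in [0, 1): a purely polar chain has no H monomers to scale.")
  if (any(a < 0)) abort("`a` must be non-negative.")
  a / (1 - X_P)
}

#' Nonbonded pair energy and force
#'
#' Evaluates the hydropathy-scaled Lennard-Jones pair potential
#' \deqn{U(r) = U_{LJ}(r) + (1-\lambda)\epsilon \quad (r \le 2^{1/6}\sigma),}
#' \deqn{U(r) = \lambda\, U_{LJ}(r) \quad (2^{1/6}\sigma < r \le r_{cut}),}
#' and 0 beyond the cutoff, with
#' \eqn{U_{LJ} = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}. The form is
#' continuous at the crossover for every \eqn{\lambda} and its well depth is
#' exactly \eqn{\lambda\epsilon}.
#'
#' @param r separation(s), nm, `> 0`.
#' @param lambda_ij pair hydropathy (scalar).
#' @param ff an [hp_forcefield()].
#' @return Energy in kcal/mol (`pair_energy`) or radial force `-dU/dr` in
#'   kcal/(mol nm) (`pair_force`), vectorized over `r`.
#' @export
pair_energy <- function(r, lambda_ij, ff) {
  if (any(r <= 0)) abort("pair separation must be positive.")
  sr6 <- (ff$sigma / r)^6
  ulj <- 4 * ff$epsilon * (sr6^2 - sr6)
  rmin <- 2^(1 / 6) * ff$sigma
  u <- ifelse(r <= rmin, ulj + (1 - lambda_ij) * ff$epsilon, lambda_ij * ulj)
  ifelse(r > ff$r_cut, 0, u)
}

#' @rdname pair_energy
#' @export
pair_force <- function(r, lambda_ij, ff) {
  if (any(r <= 0)) abort("pair separation must be positive.")
  sr6 <- (ff$sigma / r)^6
  flj <- 24 * ff$epsilon * (2 * sr6^2 - sr6) / r
  rmin <- 2^(1 / 6) * ff$sigma
  f <- ifelse(r <= rmin, flj, lambda_ij * flj)
  ifelse(r > ff$r_cut, 0, f)
}

#' Harmonic bond energy
#'
#' `U(r) = k_b (r - r0)^2` (the prefactor convention absorbs any 1/2 into
#' `k_b`).
#'
#' @inheritParams pair_energy
#' @return kcal/mol, vectorized over `r`.
#' @export
bond_energy <- function(r, ff) {
  if (any(r < 0)) abort("bond length must be non-negative.")
  ff$k_b * (r - ff$r0)^2
}

#' Total nonbonded energy of a configuration
#'
#' Sums the pair potential over all non-bonded pairs (1-2 bonded neighbours
#' excluded) within the cutoff under the minimum-image convention, using a
#' cell list.
#'
#' @param state an [hp_state] (see [build_single_chain()]).
#' @param ff an [hp_forcefield()].
#' @return Nonbonded potential energy, kcal/mol.
#' @export
system_nonbonded_energy <- function(state, ff) {
  stopifnot(inherits(state, "hp_state"))
  cpp_nonbonded_energy(state$positions, type_index(state$types),
                       as.integer(state$chain_ids), state$box,
                       ff$epsilon, ff$sigma, ff$r_cut, ff$lambda_table)
}

# H -> 0, P -> 1 for the compiled kernels
type_index <- function(types) {
  idx <- match(types, c("H", "P")) - 1L
  if (anyNA(idx)) abort("particle types must be 'H' or 'P'.")
  as.integer(idx)
}

#' Serialize a force field to / from a YAML-friendly list
#' @param ff an [hp_forcefield()].
#' @return `ff_to_list()` a plain list; `ff_from_list()` an `hp_forcefield`.
#' @export
ff_to_list <- function(ff) {
  list(model = ff$model, lambda_H = ff$lambda_H, epsilon = ff$epsilon,
       sigma = ff$sigma, k_b = ff$k_b, r0 = ff$r0, r_cut = ff$r_cut)
}

#' @rdname ff_to_list
#' @param x a list as produced by `ff_to_list()`.
#' @export
ff_from_list <- function(x) {
  hp_forcefield(model = x$model, lambda_H = x$lambda_H, epsilon = x$epsilon,
                sigma = x$sigma, k_b = x$k_b, r0 = x$r0, r_cut = x$r_cut)
}
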