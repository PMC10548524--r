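## spincross: nonadiabatic (spin-forbidden) kinetics.
##
## A spin-forbidden step proceeds through the minimum-energy crossing point
## (MECP) between the two spin surfaces; its effective barrier is the MECP
## energy plus a penalty for the finite probability p of hopping between
## surfaces at the crossing. Within nonadiabatic transition-state theory the
## hopping probability acts as a transmission coefficient, so the penalty is
## -kB T ln(p).

#' Spin-crossing parameter set
#'
#' @param hop_probability triplet-to-singlet hopping probability p, in
#'   (0, 1].
#' @param temperature K (> 0). Default 298.15 K.
#' @param e_mecp MECP energy above the reactant complex, kcal/mol.
#' @param e_competing energy of the competing (spin-allowed) transition
#'   state above the reactants, kcal/mol.
#' @param soc_cm spin-orbit coupling, cm^-1 (optional bookkeeping; the
#'   hopping probability is consumed as an input, not re-derived from SOC).
#' @return An object of class `spin_crossing_params`.
#' @export
spin_crossing_params <- function(hop_probability, temperature = 298.15,
                                 e_mecp, e_competing, soc_cm = NULL) {
  if (!.is_num1(hop_probability) || hop_probability <= 0 ||
      hop_probability > 1)
    .stopf("hop_probability must be in (0, 1]")
  if (!.is_num1(temperature) || temperature <= 0)
    .stopf("temperature must be > 0")
  if (!.is_num1(e_mecp) || !.is_num1(e_competing))
    .stopf("e_mecp and e_competing must be single finite energies (kcal/mol)")
  structure(list(hop_probability = hop_probability,
                 temperature = temperature, e_mecp = e_mecp,
                 e_competing = e_competing, soc_cm = soc_cm),
            class = "spin_crossing_params")
}

#' Barrier increase from a finite surface-hopping probability
#'
#' `-kB * T * ln(p)` in kcal/mol with kB = 1.9872e-3 kcal/(mol K): the
#' effective barrier penalty of a spin-forbidden step whose crossing is
#' attempted with success probability p. At p = 0.005 and 298.15 K this is
#' 3.14 kcal/mol (3.1 to one decimal); p = 1 (a spin-allowed step) gives 0.
#' The round trip `exp(-correction / (kB T))` returns p exactly.
#'
#' @param p hopping probability, in (0, 1] (vectorized).
#' @param temperature K (> 0). Default 298.15.
#' @return barrier increase, kcal/mol.
#' @export
barrier_correction <- function(p, temperature = 298.15) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    .stopf("p must be in (0, 1]")
  if (!.is_num1(temperature) || temperature <= 0)
    .stopf("temperature must be > 0")
  -.kB * temperature * log(p)
}

#' Effective spin-forbidden barrier and rate-limiting verdict
#'
#' The effective intersystem-crossing (ISC) barrier is the MECP energy plus
#' [barrier_correction()] at the given hopping probability. It is compared
#' with the competing spin-allowed barrier: the step with the higher
#' effective barrier is rate limiting. Equality (within 1e-9 kcal/mol) is
#' reported as `"tie"` rather than silently broken.
#'
#' @param params a [spin_crossing_params()].
#' @return list: `correction_kcal`, `effective_isc_barrier_kcal`,
#'   `competing_barrier_kcal`, `verdict` ("ISC-limiting",
#'   "competing-step-limiting" or "tie").
#' @export
effective_barrier <- function(params) {
  stopifnot(inherits(params, "spin_crossing_params"))
  corr <- barrier_correction(params$hop_probability, params$temperature)
  eff <- params$e_mecp + corr
  verdict <- if (abs(eff - params$e_competing) < 1e-9) "tie"
    else if (eff > params$e_competing) "ISC-limiting"
    else "competing-step-limiting"
  list(correction_kcal = corr,
       effective_isc_barrier_kcal = eff,
       competing_barrier_kcal = params$e_competing,
       verdict = verdict)
}

#' Double-passage Landau-Zener hopping probability
#'
#' Weak-coupling Landau-Zener estimate of the surface-hopping probability at
#' a crossing seam, with a thermally averaged crossing velocity. The
#' single-passage hopping probability is
#' `p1 = 1 - exp(-2 pi H12^2 / (hbar v dF))` with
#' `v = sqrt(2 kB T / (pi mu))` (the mean 1D thermal speed towards the
#' seam), and the double-passage probability accounts for the second chance
#' on the way back: `p = 1 - (1 - p1)^2`.
#'
#' Unit handling: `h12_cm` (cm^-1) is converted with E = h c sigma;
#' `slope_difference` (kcal mol^-1 A^-1, the difference of surface gradients
#' at the seam) to J/m per molecule; `reduced_mass` (amu) to kg. The result
#' is monotonically increasing in `h12_cm`, quadratic in it in the
#' weak-coupling regime, and saturates at 1. This utility documents a
#' standard formula for exploration; measured hopping probabilities should
#' be supplied to [spin_crossing_params()] directly.
#'
#' @param h12_cm spin-orbit coupling matrix element, cm^-1 (>= 0).
#' @param slope_difference |difference of surface slopes| at the crossing,
#'   kcal mol^-1 A^-1 (> 0).
#' @param reduced_mass effective reduced mass along the crossing coordinate,
#'   amu (> 0).
#' @param temperature K (> 0).
#' @return hopping probability in \[0, 1).
#' @export
lz_hop_probability <- function(h12_cm, slope_difference, reduced_mass,
                               temperature = 298.15) {
  if (any(!is.finite(h12_cm)) || any(h12_cm < 0))
    .stopf("h12_cm must be >= 0")
  if (!.is_num1(slope_difference) || slope_difference <= 0 ||
      !.is_num1(reduced_mass) || reduced_mass <= 0 ||
      !.is_num1(temperature) || temperature <= 0)
    .stopf("slope_difference, reduced_mass and temperature must be > 0")
  h_planck <- 6.62607015e-34       # J s
  hbar <- h_planck / (2 * pi)
  c_cm <- 2.99792458e10            # cm/s
  kB_J <- 1.380649e-23             # J/K
  amu <- 1.66053906660e-27         # kg
  avogadro <- 6.02214076e23
  H12_J <- h_planck * c_cm * h12_cm
  dF_J_m <- slope_difference * 4184 / avogadro / 1e-10
  mu_kg <- reduced_mass * amu
  v <- sqrt(2 * kB_J * temperature / (pi * mu_kg))
  p1 <- 1 - exp(-2 * pi * H12_J^2 / (hbar * v * dF_J_m))
  1 - (1 - p1)^2
}
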