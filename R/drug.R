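#' Define a weak-base drug substance
#'
#' Physicochemical model of the dissolving drug: up to two basic pKa values,
#' intrinsic (neutral-species) solubility, an optional solubility product
#' with chloride for the hydrochloride ion pair (common-ion cap), a lumped
#' filter/octanol permeation coefficient, and a first-order
#' supersaturation-decay (precipitation) rate constant.
#'
#' @param name drug label.
#' @param base_pkas numeric vector of 0-2 basic pKa values (sorted
#'   descending internally; the first is the most basic site).
#' @param intrinsic_solubility_mg_ml solubility of the neutral species S0
#'   (mg/mL), `> 0`.
#' @param mol_weight_g_mol molar mass (g/mol); needed to convert the molar
#'   chloride solubility product into mass-based solubility.
#' @param chloride_ksp optional solubility product of the mono-protonated
#'   drug-chloride ion pair, (mol/L)^2; `NULL` disables the common-ion cap.
#' @param permeation_coefficient_cm_min lumped permeation coefficient
#'   (cm/min), `>= 0`.
#' @param precipitation_rate_per_min first-order decay rate of
#'   supersaturation (1/min), `>= 0`.
#' @return An object of class `drug_substance`.
#' @export
#' @examples
#' d <- drug_substance("toy base", base_pkas = 6.7, intrinsic_solubility_mg_ml = 0.01)
#' equilibrium_solubility(d, ph = 5.7) # 0.11 mg/mL
drug_substance <- function(name, base_pkas = numeric(0),
                           intrinsic_solubility_mg_ml,
                           mol_weight_g_mol = 400,
                           chloride_ksp = NULL,
                           permeation_coefficient_cm_min = 0,
                           precipitation_rate_per_min = 0) {
  stopifnot(
    length(base_pkas) <= 2,
    intrinsic_solubility_mg_ml > 0,
    mol_weight_g_mol > 0,
    is.null(chloride_ksp) || chloride_ksp > 0,
    permeation_coefficient_cm_min >= 0,
    precipitation_rate_per_min >= 0
  )
  structure(
    list(
      name = name,
      base_pkas = sort(as.numeric(base_pkas), decreasing = TRUE),
      intrinsic_solubility_mg_ml = intrinsic_solubility_mg_ml,
      mol_weight_g_mol = mol_weight_g_mol,
      chloride_ksp = chloride_ksp,
      permeation_coefficient_cm_min = permeation_coefficient_cm_min,
      precipitation_rate_per_min = precipitation_rate_per_min
    ),
    class = "drug_substance"
  )
}

#' @export
print.drug_substance <- function(x, ...) {
  cat("<drug_substance>", x$name, "\n")
  cat("  pKa:", if (length(x$base_pkas)) paste(x$base_pkas, collapse = ", ") else "none (pH-independent)", "\n")
  cat(sprintf("  S0: %g mg/mL  MW: %g g/mol\n", x$intrinsic_solubility_mg_ml, x$mol_weight_g_mol))
  if (!is.null(x$chloride_ksp)) cat(sprintf("  chloride Ksp: %g (mol/L)^2\n", x$chloride_ksp))
  cat(sprintf(
    "  P: %g cm/min  precipitation rate: %g /min\n",
    x$permeation_coefficient_cm_min, x$precipitation_rate_per_min
  ))
  invisible(x)
}

#' pH- and chloride-dependent equilibrium solubility
#'
#' Henderson-Hasselbalch total solubility of a weak base in equilibrium
#' with its free-base solid,
#' `S = S0 (1 + 10^(pKa1 - pH) + 10^(pKa1 + pKa2 - 2 pH))`
#' (terms present per number of pKa values), optionally capped by the
#' chloride common-ion effect: when a solubility product `Ksp` for the
#' mono-protonated drug-chloride pair is set and chloride is present, the
#' mono-protonated species cannot exceed `Ksp / [Cl-]`, so total solubility
#' is the minimum of the free-base branch and the salt branch
#' `MW * (Ksp / [Cl-]) * (1 + 10^(pH - pKa1) + 10^(pKa2 - pH))`.
#' The result is continuous in pH (the two branches cross smoothly) and
#' non-increasing in chloride.
#'
#' @param drug a [drug_substance()].
#' @param ph pH (vectorized).
#' @param chloride_mm chloride concentration (mM), `>= 0` (length 1 or
#'   recycled against `ph`).
#' @return solubility in mg/mL, vectorized over `ph`.
#' @export
equilibrium_solubility <- function(drug, ph, chloride_mm = 0) {
  stopifnot(inherits(drug, "drug_substance"))
  stopifnot(all(ph >= 0 & ph <= 14), all(chloride_mm >= 0))
  s0 <- drug$intrinsic_solubility_mg_ml
  pk <- drug$base_pkas
  if (length(pk) == 0) {
    return(rep(s0, length(ph)))
  }
  ion1 <- 10^(pk[1] - ph)
  ion2 <- if (length(pk) == 2) 10^(pk[1] + pk[2] - 2 * ph) else 0
  s_hh <- s0 * (1 + ion1 + ion2)
  if (is.null(drug$chloride_ksp) || all(chloride_mm <= 0)) {
    return(s_hh)
  }
  cl_m <- rep_len(chloride_mm, length(ph)) / 1000
  # molar cap on the mono-protonated species; Inf (no cap) at zero chloride
  bhp_cap_m <- ifelse(cl_m > 0, drug$chloride_ksp / cl_m, Inf)
  ratio2 <- if (length(pk) == 2) 10^(pk[2] - ph) else 0
  s_salt <- drug$mol_weight_g_mol * bhp_cap_m * (1 + 10^(ph - pk[1]) + ratio2)
  pmin(s_hh, s_salt)
}

#' Supersaturation decay (precipitation) flux
#'
#' First-order relaxation of a supersaturated solution toward its current
#' equilibrium solubility: returns
#' `-rate * (dissolved - solubility)` (mg/mL/min) when dissolved exceeds
#' solubility, else 0. In the transit simulation the precipitated mass
#' re-enters the solid pool and may redissolve if conditions change.
#'
#' @param drug a [drug_substance()].
#' @param dissolved_mg_ml dissolved concentration (mg/mL), `>= 0`.
#' @param solubility_mg_ml equilibrium solubility at the current pH and
#'   chloride (mg/mL), `>= 0`.
#' @return concentration rate of change (mg/mL/min), `<= 0`.
#' @export
supersaturation_flux <- function(drug, dissolved_mg_ml, solubility_mg_ml) {
  stopifnot(inherits(drug, "drug_substance"))
  stopifnot(all(dissolved_mg_ml >= 0), all(solubility_mg_ml >= 0))
  ifelse(
    dissolved_mg_ml > solubility_mg_ml,
    -drug$precipitation_rate_per_min * (dissolved_mg_ml - solubility_mg_ml),
    0
  )
}
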