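#' Packaged drug/formulation archetype fixtures
#'
#' Returns one of four calibrated archetype fixtures spanning the
#' behaviours the device was designed to discriminate:
#'
#' * `metoprolol_like` - a freely soluble, pH-independent drug (20 mg
#'   tablet) whose dissolution is agitation-limited only. Calibrated so
#'   that dissolution reaches 80% of dose by about 30, 45 and 60 min at
#'   200, 100 and 50 rpm.
#' * `dipyridamole_like` - a weak base (25 mg tablet), highly soluble in
#'   acid and nearly insoluble at neutral pH, showing gastric
#'   supersaturation followed by precipitation after the pH shift when
#'   agitation is strong, and slow, incomplete dissolution (< 25% of dose)
#'   when disintegration is agitation-limited. The single effective pKa
#'   (6.27) and intrinsic solubility (0.0038 mg/mL) are least-squares
#'   calibrated to the anchor solubilities > 100 mg/mL below pH 2,
#'   7 mg/mL at pH 3 and 0.006 mg/mL at pH 6.5.
#' * `naftopidil_ordinary` / `naftopidil_od` - a di-basic weak base
#'   (pKa 3.7 and 6.7, 25 mg tablets) with very low neutral solubility
#'   (< 0.1 ug/mL above pH 5) whose mono-protonated chloride ion pair has
#'   a solubility product, so in HCl-rich gastric media the dissolving
#'   drug precipitates at the tablet surface as a gel that inhibits
#'   disintegration. The two products share the drug substance and differ
#'   only in disintegration behaviour: the orally disintegrating (OD)
#'   product disperses very fast in water but gels badly in acidic
#'   chloride media; the ordinary tablet disintegrates moderately
#'   everywhere, but is strongly agitation-dependent. The chloride Ksp is
#'   not an observed constant but a calibration artifact (synthetic),
#'   chosen together with the disintegration time constants so the
#'   simulated permeation similarity reproduces the observed
#'   similar-at-100-rpm / dissimilar-at-50-rpm pattern (f2 about 60
#'   versus about 34 with water pre-dispersion).
#'
#' @param name one of `"metoprolol_like"`, `"dipyridamole_like"`,
#'   `"naftopidil_ordinary"`, `"naftopidil_od"`.
#' @return list with elements `drug` ([drug_substance()]), `formulation`
#'   ([formulation()]) and `provenance` (character vector distinguishing
#'   anchored constants from calibration artifacts).
#' @export
#' @examples
#' make_fixture("metoprolol_like")$drug
make_fixture <- function(name = c(
                           "metoprolol_like", "dipyridamole_like",
                           "naftopidil_ordinary", "naftopidil_od"
                         )) {
  name <- match.arg(name)
  tau_tab <- function(water, acid50, acid100, acid200, neutral) {
    tibble::tibble(
      medium = c("water", "acidic_chloride", "acidic_chloride", "acidic_chloride", "neutral"),
      rpm = c(100, 50, 100, 200, 100),
      tau_min = c(water, acid50, acid100, acid200, neutral)
    )
  }
  naftopidil <- drug_substance(
    "naftopidil-like",
    base_pkas = c(6.7, 3.7),
    intrinsic_solubility_mg_ml = 1.5e-6,
    mol_weight_g_mol = 392.5,
    chloride_ksp = 1e-6,
    permeation_coefficient_cm_min = 0.02,
    precipitation_rate_per_min = 0.02
  )
  switch(name,
    metoprolol_like = list(
      drug = drug_substance(
        "metoprolol-like",
        base_pkas = numeric(0),
        intrinsic_solubility_mg_ml = 50,
        mol_weight_g_mol = 267.4,
        permeation_coefficient_cm_min = 0.01,
        precipitation_rate_per_min = 0
      ),
      formulation = formulation(
        "immediate-release tablet 20 mg",
        dose_mg = 20,
        tau = tau_tab(0.5, 0.5, 0.5, 0.5, 0.5),
        k_ref = 1.49e-4, rpm_exponent = 0.53,
        role = "reference"
      ),
      provenance = c(
        "anchored: pH-independent, non-limiting solubility; dose 20 mg",
        "calibrated: k_ref, rpm_exponent to 80% dissolved near 30/45/60 min at 200/100/50 rpm"
      )
    ),
    dipyridamole_like = list(
      drug = drug_substance(
        "dipyridamole-like",
        base_pkas = 6.27,
        intrinsic_solubility_mg_ml = 0.0038,
        mol_weight_g_mol = 504.6,
        permeation_coefficient_cm_min = 0.03,
        precipitation_rate_per_min = 0.015
      ),
      formulation = formulation(
        "immediate-release tablet 25 mg",
        dose_mg = 25,
        tau = tau_tab(1, 60, 35, 0.7, 35),
        k_ref = 0.05, rpm_exponent = 0.5,
        role = "reference"
      ),
      provenance = c(
        "anchored: solubility >100 mg/mL below pH 2, 7 mg/mL at pH 3, 0.006 mg/mL at pH 6.5; dose 25 mg",
        "calibrated: effective pKa 6.27 and S0 0.0038 mg/mL (least squares on the anchors)",
        "calibrated: disintegration taus so dissolution is complete within 5 min at 200 rpm and < 25% of dose at 50/100 rpm with a 10-min infusion"
      )
    ),
    naftopidil_ordinary = list(
      drug = naftopidil,
      formulation = formulation(
        "ordinary tablet 25 mg",
        dose_mg = 25,
        tau = tau_tab(1.2, 20, 0.7, 0.35, 5),
        k_ref = 0.2, rpm_exponent = 0.5,
        role = "reference"
      ),
      provenance = c(
        "anchored: pKa 3.7/6.7; solubility < 0.1 ug/mL above pH 5; dose 25 mg",
        "synthetic: chloride Ksp 1e-6 (mol/L)^2 is a calibration artifact (no printed value)",
        "calibrated: taus/k_ref so the ordinary-vs-OD permeation f2 is ~60 at 100 rpm and ~34 at 50 rpm with water pre-dispersion"
      )
    ),
    naftopidil_od = list(
      drug = naftopidil,
      formulation = formulation(
        "orally disintegrating tablet 25 mg",
        dose_mg = 25,
        tau = tau_tab(0.3, 40, 20, 10, 5),
        k_ref = 0.2, rpm_exponent = 0.5,
        role = "test"
      ),
      provenance = c(
        "anchored: shares the drug substance with naftopidil_ordinary; differs only in disintegration",
        "anchored: fast disintegration in water, gel-inhibited in acidic chloride media",
        "calibrated: taus as for naftopidil_ordinary"
      )
    )
  )
}
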