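#' Design the concentrated infusate by inverse mass balance
#'
#' Computes the composition of the infusate ("pre" fluid) of volume
#' `vf_ml - v0_ml` that, infused into `v0_ml` of the initial fluid, yields
#' exactly `vf_ml` of the final fluid: per species,
#' `C_pre = (C_final * Vf - C_initial * V0) / (Vf - V0)`, and likewise for
#' the strong-ion offset. In the standard device this turns 40 mL of
#' gastric fluid into 100 mL of intestinal fluid with 60 mL of concentrated
#' infusate (nominally "1.67x concentrated" = `Vf / (Vf - V0)`, see
#' [concentration_multiple()]; the exact balance differs slightly from
#' uniform scaling for species already present in the initial fluid).
#'
#' @param initial `fluid_composition` already in the chamber.
#' @param v0_ml its volume (mL).
#' @param final `fluid_composition` the mixture must equal.
#' @param vf_ml final volume (mL), `> v0_ml`.
#' @return A `fluid_composition` for the infusate.
#' @section Errors: an infeasible-design error is raised when the initial
#'   fluid already over-supplies a species (negative required infusate
#'   concentration).
#' @export
#' @examples
#' pre <- design_pre_fluid(recipe_fassgf(ph = 1.6), 40, recipe_fassif(ph = 6.5), 100)
#' tidy(pre)
design_pre_fluid <- function(initial, v0_ml, final, vf_ml) {
  stopifnot(inherits(initial, "fluid_composition"), inherits(final, "fluid_composition"))
  stopifnot(v0_ml > 0, vf_ml > v0_ml)
  v_pre <- vf_ml - v0_ml
  pre <- (final$species_totals_mm * vf_ml - initial$species_totals_mm * v0_ml) / v_pre
  neg <- pre < -1e-9
  if (any(neg)) {
    rlang::abort(
      paste0(
        "infeasible infusate design: initial fluid over-supplies ",
        paste(names(pre)[neg], collapse = ", ")
      ),
      class = "transitsim_infeasible_design"
    )
  }
  pre[pre < 0] <- 0
  off <- (final$strong_ion_offset_mm * vf_ml - initial$strong_ion_offset_mm * v0_ml) / v_pre
  fluid_composition(
    pre[pre > 0],
    strong_ion_offset_mm = off,
    label = paste0("pre-", final$label),
    constants = final$constants
  )
}

#' Nominal concentration multiple of the infusate
#'
#' The uniform factor `Vf / (Vf - V0)` by which the final recipe would be
#' concentrated if the infusate were a simple dilution stock; 1.67 for the
#' standard 40 mL to 100 mL design. Reported alongside the exact per-species
#' design, which it only approximates for species present initially.
#'
#' @param v0_ml initial volume (mL).
#' @param vf_ml final volume (mL).
#' @return dimensionless multiple.
#' @export
#' @examples
#' concentration_multiple(40, 100) # 1.67
concentration_multiple <- function(v0_ml, vf_ml) {
  stopifnot(vf_ml > v0_ml, v0_ml >= 0)
  vf_ml / (vf_ml - v0_ml)
}

#' Constant-rate infusion mixing schedule
#'
#' One infusion run: `infusate_volume_ml` of infusate delivered into
#' `initial_volume_ml` of initial fluid at constant rate over
#' `infusion_min` minutes. Volume is piecewise linear in time and constant
#' after the infusion ends; species amounts are conserved.
#'
#' @param initial_fluid,infusate_fluid `fluid_composition` objects.
#' @param initial_volume_ml,infusate_volume_ml volumes (mL), `> 0`.
#' @param infusion_min infusion duration (min), `> 0`.
#' @return An object of class `mixing_schedule`.
#' @export
mixing_schedule <- function(initial_fluid, infusate_fluid,
                            initial_volume_ml = 40, infusate_volume_ml = 60,
                            infusion_min = 10) {
  stopifnot(
    inherits(initial_fluid, "fluid_composition"),
    inherits(infusate_fluid, "fluid_composition"),
    initial_volume_ml > 0, infusate_volume_ml > 0, infusion_min > 0
  )
  structure(
    list(
      initial_fluid = initial_fluid,
      infusate_fluid = infusate_fluid,
      initial_volume_ml = initial_volume_ml,
      infusate_volume_ml = infusate_volume_ml,
      infusion_min = infusion_min,
      rate_ml_min = infusate_volume_ml / infusion_min
    ),
    class = "mixing_schedule"
  )
}

# vectorized well-mixed state over times; returns list(volume_ml, totals_mm
# matrix [time x species], offset_mm)
.mixing_state_many <- function(schedule, times) {
  te <- pmin(times, schedule$infusion_min)
  v0 <- schedule$initial_volume_ml
  q <- schedule$rate_ml_min
  v <- v0 + q * te
  c0 <- schedule$initial_fluid$species_totals_mm
  cp <- schedule$infusate_fluid$species_totals_mm
  # amounts (umol-equivalent: mM * mL) mixed, then back to concentration
  totals <- (outer(rep(v0, length(te)), c0) + outer(q * te, cp)) / v
  colnames(totals) <- names(c0)
  off <- (v0 * schedule$initial_fluid$strong_ion_offset_mm +
    q * te * schedule$infusate_fluid$strong_ion_offset_mm) / v
  list(volume_ml = v, totals_mm = totals, offset_mm = off)
}

#' Well-mixed chamber state at a given time
#'
#' Closed-form mass balance of constant-rate infusion into a well-mixed
#' chamber: `C_i(t) = (V0 C_i0 + Q t C_i,pre) / (V0 + Q t)`, clamped at the
#' end of infusion.
#'
#' @param schedule a [mixing_schedule()].
#' @param t_min time since the start of infusion (min), `>= 0`.
#' @return list with `volume_ml` and `fluid` (a `fluid_composition`).
#' @export
mixing_state <- function(schedule, t_min) {
  stopifnot(inherits(schedule, "mixing_schedule"), t_min >= 0, length(t_min) == 1)
  st <- .mixing_state_many(schedule, t_min)
  totals <- st$totals_mm[1, ]
  names(totals) <- schedule$initial_fluid$constants$species
  list(
    volume_ml = st$volume_ml[1],
    fluid = fluid_composition(
      totals[totals > 0],
      strong_ion_offset_mm = st$offset_mm[1],
      label = sprintf("%s + %s @ %.3g min", schedule$initial_fluid$label,
                      schedule$infusate_fluid$label, t_min),
      constants = schedule$initial_fluid$constants
    )
  )
}

#' Per-species infusate design report
#'
#' Tabulates, for every species, the initial and final recipe
#' concentrations, the exact infusate concentration from
#' [design_pre_fluid()], and what uniform scaling by the nominal multiple
#' would give instead. This is the designed-fluid report of the pipeline's
#' fluid-design stage.
#'
#' @inheritParams design_pre_fluid
#' @return A tibble with columns `species`, `initial_mM`, `final_mM`,
#'   `infusate_mM`, `uniform_scaling_mM`; the nominal multiple and the
#'   infusate composition are attached as attributes `multiple` and
#'   `infusate`.
#' @export
#' @examples
#' design_fluid_report(recipe_fassgf(ph = 1.6), 40, recipe_fassif(ph = 6.5), 100)
design_fluid_report <- function(initial, v0_ml, final, vf_ml) {
  pre <- design_pre_fluid(initial, v0_ml, final, vf_ml)
  mult <- concentration_multiple(v0_ml, vf_ml)
  out <- tibble::tibble(
    species = names(final$species_totals_mm),
    initial_mM = unname(initial$species_totals_mm),
    final_mM = unname(final$species_totals_mm),
    infusate_mM = unname(pre$species_totals_mm),
    uniform_scaling_mM = unname(final$species_totals_mm) * mult
  )
  attr(out, "multiple") <- mult
  attr(out, "infusate") <- pre
  out
}
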