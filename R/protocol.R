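#' Define a formulation (drug product)
#'
#' A tablet or orally disintegrating (OD) product: dose, first-order
#' disintegration time constants per medium class and paddle speed, and the
#' dissolution rate constant of the disintegrated particles. The medium
#' classes capture the observed disintegration chemistry: `water`
#' (pre-dispersion in distilled water), `acidic_chloride` (strongly acidic,
#' HCl-rich gastric fluid in which hydrochloride-forming bases can gel on
#' the tablet surface), and `neutral` (after the pH shift passes 5).
#'
#' @param label product label.
#' @param dose_mg dose per tablet (mg), `> 0`.
#' @param tau tibble/data frame with columns `medium`
#'   (`"water"|"acidic_chloride"|"neutral"`), `rpm`, `tau_min` (first-order
#'   disintegration time constant, min, `> 0`). Missing rpm levels are
#'   interpolated on log(rpm) within each medium.
#' @param k_ref dissolution rate constant at 100 rpm (1/min); the rate law
#'   is `k_ref (rpm/100)^rpm_exponent (avail/dose)^(2/3) (S - C) V`.
#' @param rpm_exponent agitation power-law exponent.
#' @param role `"reference"` or `"test"` product role in a bioequivalence
#'   pairing (informational).
#' @return An object of class `formulation`.
#' @export
formulation <- function(label, dose_mg, tau, k_ref, rpm_exponent = 0.5,
                        role = c("reference", "test")) {
  role <- match.arg(role)
  tau <- tibble::as_tibble(tau)
  stopifnot(
    dose_mg > 0, k_ref > 0,
    all(c("medium", "rpm", "tau_min") %in% names(tau)),
    all(tau$tau_min > 0), all(tau$rpm > 0),
    all(tau$medium %in% c("water", "acidic_chloride", "neutral"))
  )
  structure(
    list(
      label = label, dose_mg = dose_mg, tau = tau,
      k_ref = k_ref, rpm_exponent = rpm_exponent, role = role
    ),
    class = "formulation"
  )
}

#' Look up a disintegration time constant
#'
#' @param form a [formulation()].
#' @param medium one of `"water"`, `"acidic_chloride"`, `"neutral"`.
#' @param rpm paddle speed; interpolated on log(rpm) between tabulated
#'   levels, clamped outside the tabulated range.
#' @return time constant in minutes.
#' @export
disintegration_tau <- function(form, medium, rpm) {
  stopifnot(inherits(form, "formulation"))
  rows <- form$tau[form$tau$medium == medium, ]
  if (nrow(rows) == 0) {
    rlang::abort(paste0("no disintegration tau for medium '", medium, "' in ", form$label))
  }
  if (nrow(rows) == 1) {
    return(rows$tau_min)
  }
  rows <- rows[order(rows$rpm), ]
  exp(stats::approx(log(rows$rpm), log(rows$tau_min), xout = log(rpm), rule = 2)$y)
}

#' Device geometry
#'
#' Volumes and filter area of the two-chamber device: 40 mL gastric
#' starting volume, 60 mL infusate giving a 100 mL final donor volume, a
#' 30 mL (final) octanol receiver, and a 6.60 cm^2 filter that is dry at
#' the starting volume and fully wetted at the final volume.
#'
#' @param gastric_volume_ml,final_volume_ml,infusate_volume_ml,receiver_final_volume_ml
#'   volumes in mL; `final = gastric + infusate` must hold.
#' @param filter_area_cm2 maximum effective filter area (cm^2).
#' @return An object of class `device_geometry`.
#' @export
device_geometry <- function(gastric_volume_ml = 40, final_volume_ml = 100,
                            infusate_volume_ml = 60,
                            receiver_final_volume_ml = 30,
                            filter_area_cm2 = 6.60) {
  stopifnot(
    gastric_volume_ml > 0, final_volume_ml > 0, infusate_volume_ml > 0,
    receiver_final_volume_ml > 0, filter_area_cm2 > 0,
    isTRUE(all.equal(final_volume_ml, gastric_volume_ml + infusate_volume_ml))
  )
  structure(
    list(
      gastric_volume_ml = gastric_volume_ml,
      final_volume_ml = final_volume_ml,
      infusate_volume_ml = infusate_volume_ml,
      receiver_final_volume_ml = receiver_final_volume_ml,
      filter_area_cm2 = filter_area_cm2
    ),
    class = "device_geometry"
  )
}

#' Wetted filter area as a function of donor volume
#'
#' The filter is dry (zero permeation area) while the donor holds only the
#' gastric volume, becomes progressively wetted as infusion raises the
#' fluid level, and reaches the full effective area at the final volume;
#' linear in between and monotone non-decreasing.
#'
#' @param geometry a [device_geometry()].
#' @param volume_ml donor volume (mL), within
#'   `[0, final_volume_ml]` (vectorized).
#' @return wetted area (cm^2).
#' @export
#' @examples
#' wetted_area(device_geometry(), c(40, 70, 100)) # 0, 3.3, 6.6
wetted_area <- function(geometry, volume_ml) {
  stopifnot(inherits(geometry, "device_geometry"))
  if (any(volume_ml < 0 | volume_ml > geometry$final_volume_ml + 1e-9)) {
    rlang::abort("donor volume outside [0, final_volume]")
  }
  frac <- (volume_ml - geometry$gastric_volume_ml) /
    (geometry$final_volume_ml - geometry$gastric_volume_ml)
  geometry$filter_area_cm2 * pmin(pmax(frac, 0), 1)
}

#' Define a device run protocol
#'
#' One run's knobs: the initial gastric pH (standard levels 1.6, 3.0, 5.0,
#' 6.5 spanning normal to achlorhydric stomachs), the infusate infusion
#' time (10 or 20 min standard; the in-vitro surrogate of gastric emptying
#' time), paddle speed (50/100/200 rpm; agitation strength), an optional
#' 1-min pre-dispersion of the tablet in distilled water before the gastric
#' fluid is constituted (mimicking oral disintegration before the tablet
#' reaches the stomach), and the sampling schedule.
#'
#' @param initial_gastric_ph initial gastric fluid pH.
#' @param infusion_min infusion duration (min), `> 0`.
#' @param paddle_rpm paddle speed (rpm), `> 0`.
#' @param water_disintegration if `TRUE`, the first `gastric_hold_min`
#'   minute(s) are spent in distilled water, after which the medium is
#'   constituted to gastric fluid at `initial_gastric_ph`.
#' @param gastric_hold_min disintegration/dissolution phase before infusion
#'   starts (min; 1 standard).
#' @param run_min total run length (min; 120 standard).
#' @param sampling_min sampling times (min), within `[0, run_min]`.
#' @param sample_volume_ml volume withdrawn per sample (mL); 0 = ideal
#'   (non-perturbing) sampling. Used by [apply_sampling_correction()].
#' @param step_min fixed integrator step (min).
#' @param final_ph target pH of the final (intestinal) fluid.
#' @return An object of class `protocol`.
#' @export
protocol <- function(initial_gastric_ph = 1.6, infusion_min = 10,
                     paddle_rpm = 100, water_disintegration = FALSE,
                     gastric_hold_min = 1, run_min = 120,
                     sampling_min = c(0, 5, 10, 15, 20, 30, 45, 60, 90, 120),
                     sample_volume_ml = 0, step_min = 0.01, final_ph = 6.5) {
  stopifnot(
    initial_gastric_ph > 0, initial_gastric_ph < 14,
    infusion_min > 0, paddle_rpm > 0, gastric_hold_min >= 0,
    run_min > gastric_hold_min + infusion_min,
    all(sampling_min >= 0 & sampling_min <= run_min),
    !is.unsorted(sampling_min),
    sample_volume_ml >= 0, step_min > 0
  )
  structure(
    list(
      initial_gastric_ph = initial_gastric_ph,
      infusion_min = infusion_min,
      paddle_rpm = paddle_rpm,
      water_disintegration = isTRUE(water_disintegration),
      gastric_hold_min = gastric_hold_min,
      run_min = run_min,
      sampling_min = sampling_min,
      sample_volume_ml = sample_volume_ml,
      step_min = step_min,
      final_ph = final_ph
    ),
    class = "protocol"
  )
}
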