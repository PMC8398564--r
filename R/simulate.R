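#' Dissolution rate of disintegrated solid
#'
#' Agitation- and saturation-dependent dissolution rate law
#' `rate = k_ref (rpm/100)^a * (avail/dose)^(2/3) * (S - C) * V` (mg/min),
#' zero when there is no disintegrated solid or the solution is at or above
#' saturation (precipitation of a supersaturated solution is handled
#' separately by [supersaturation_flux()]). The 2/3 power of the remaining
#' solid fraction is the shrinking-surface (cube-root law) geometry of a
#' monodisperse particle population.
#'
#' @param drug a [drug_substance()].
#' @param form a [formulation()] (supplies `k_ref`, `rpm_exponent`, dose).
#' @param avail_mg disintegrated, undissolved solid (mg).
#' @param dissolved_mg dissolved mass in the donor (mg).
#' @param volume_ml donor volume (mL).
#' @param solubility_mg_ml equilibrium solubility at current conditions.
#' @param rpm paddle speed.
#' @return dissolution rate (mg/min), `>= 0`.
#' @export
dissolution_rate <- function(drug, form, avail_mg, dissolved_mg, volume_ml,
                             solubility_mg_ml, rpm) {
  stopifnot(inherits(drug, "drug_substance"), inherits(form, "formulation"))
  stopifnot(avail_mg >= 0, dissolved_mg >= 0, volume_ml > 0, rpm > 0)
  conc <- dissolved_mg / volume_ml
  kd <- form$k_ref * (rpm / 100)^form$rpm_exponent
  rate <- kd * (avail_mg / form$dose_mg)^(2 / 3) *
    (solubility_mg_ml - conc) * volume_ml
  max(rate, 0)
}

# Precompute forcing functions (volume, pH, chloride, solubility, wetted
# area, disintegration rate constant) on the uniform half-step grid.
.transit_forcings <- function(drug, form, prot, geometry, gastric, intestinal) {
  pre <- design_pre_fluid(
    gastric, geometry$gastric_volume_ml,
    intestinal, geometry$final_volume_ml
  )
  sched <- mixing_schedule(
    gastric, pre,
    initial_volume_ml = geometry$gastric_volume_ml,
    infusate_volume_ml = geometry$infusate_volume_ml,
    infusion_min = prot$infusion_min
  )
  h <- prot$step_min
  n_steps <- round(prot$run_min / h)
  if (abs(n_steps * h - prot$run_min) > 1e-9) {
    rlang::abort("run_min must be an integer multiple of step_min")
  }
  tg <- seq(0, prot$run_min, by = h / 2) # half-step grid, 2*n_steps + 1 points
  s <- pmin(pmax(tg - prot$gastric_hold_min, 0), prot$infusion_min)

  # pH/chloride/volume from the mixing trajectory (solved on unique times)
  su <- unique(s)
  traj <- ph_trajectory(sched, su)
  idx <- match(s, su)
  ph <- traj$pH[idx]
  cl <- traj$chloride_mM[idx]
  vol <- traj$volume_mL[idx]

  water <- prot$water_disintegration & (tg < prot$gastric_hold_min)
  ph[water] <- 7.0
  cl[water] <- 0
  vol[water] <- geometry$gastric_volume_ml

  sol <- equilibrium_solubility(drug, ph, cl)
  area <- wetted_area(geometry, pmin(vol, geometry$final_volume_ml))

  medium <- ifelse(water, "water", ifelse(ph < 5, "acidic_chloride", "neutral"))
  kdis <- rep(NA_real_, length(tg))
  for (m in unique(medium)) {
    kdis[medium == m] <- 1 / disintegration_tau(form, m, prot$paddle_rpm)
  }

  list(
    tg = tg, n_steps = n_steps, h = h,
    volume = vol, ph = ph, chloride = cl, solubility = sol,
    area = area, kdis = kdis, medium = medium, schedule = sched
  )
}

# Fixed-step classical RK4 over the four-pool state
# (intact, available solid, dissolved, receiver), forcings index-aligned
# to the half-step grid. Returns state matrix on the full-step grid.
.integrate_transit <- function(drug, form, prot, fc) {
  kd <- form$k_ref * (prot$paddle_rpm / 100)^form$rpm_exponent
  p_coef <- drug$permeation_coefficient_cm_min
  p_rate <- drug$precipitation_rate_per_min
  dose <- form$dose_mg
  vol <- fc$volume
  sol <- fc$solubility
  area <- fc$area
  kdis <- fc$kdis

  deriv <- function(u, i) {
    intact <- max(u[1], 0)
    avail <- max(u[2], 0)
    v <- vol[i]
    conc <- u[3] / v
    s <- sol[i]
    rel <- kdis[i] * intact
    if (conc < s) {
      dis <- kd * (avail / dose)^(2 / 3) * (s - conc) * v
      prec <- 0
    } else {
      dis <- 0
      prec <- p_rate * (conc - s) * v
    }
    perm <- p_coef * area[i] * max(conc, 0)
    c(-rel, rel - dis + prec, dis - prec - perm, perm)
  }

  n <- fc$n_steps
  h <- fc$h
  out <- matrix(0, nrow = n + 1, ncol = 4)
  u <- c(dose, 0, 0, 0)
  out[1, ] <- u
  for (k in seq_len(n)) {
    i0 <- 2L * k - 1L
    k1 <- deriv(u, i0)
    k2 <- deriv(u + h / 2 * k1, i0 + 1L)
    k3 <- deriv(u + h / 2 * k2, i0 + 1L)
    k4 <- deriv(u + h * k3, i0 + 2L)
    u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k + 1, ] <- u
  }
  out
}

#' Simulate a full device run
#'
#' Integrates one run of the transfer device for a drug/formulation pair
#' under a [protocol()]: first-order tablet disintegration (with the medium
#' class active at each instant: water pre-dispersion if enabled, then
#' acidic chloride-rich gastric fluid, switching to neutral as the pH shift
#' passes 5), shrinking-surface dissolution, first-order precipitation of
#' supersaturated drug back into the solid pool, and permeation through the
#' progressively wetted filter into the octanol receiver (treated as a
#' perfect sink). pH, chloride and volume follow the infusion mixing
#' trajectory of the designed concentrated infusate. Integration is
#' fixed-step classical Runge-Kutta (default 0.01 min) for platform-stable
#' reproducibility.
#'
#' @param drug a [drug_substance()].
#' @param form a [formulation()].
#' @param prot a [protocol()].
#' @param geometry a [device_geometry()].
#' @param gastric,intestinal initial and final `fluid_composition`s; by
#'   default the shipped recipes calibrated to `prot$initial_gastric_ph`
#'   and `prot$final_ph`.
#' @return A tibble of class `profile_set` with columns `time_min`,
#'   `dissolved_pct`, `permeated_pct`, `solid_pct` (all % of dose),
#'   `pH`, `volume_mL`, evaluated at `prot$sampling_min`. Attributes:
#'   `drug`, `formulation`, `protocol`, `geometry`, `dose_mg`.
#' @export
#' @examples
#' fx <- make_fixture("metoprolol_like")
#' prof <- simulate_transit(fx$drug, fx$formulation,
#'   protocol(paddle_rpm = 200, step_min = 0.05)
#' )
#' prof
simulate_transit <- function(drug, form, prot, geometry = device_geometry(),
                             gastric = NULL, intestinal = NULL) {
  stopifnot(
    inherits(drug, "drug_substance"), inherits(form, "formulation"),
    inherits(prot, "protocol"), inherits(geometry, "device_geometry")
  )
  if (is.null(gastric)) gastric <- recipe_fassgf(ph = prot$initial_gastric_ph)
  if (is.null(intestinal)) intestinal <- recipe_fassif(ph = prot$final_ph)
  fc <- .transit_forcings(drug, form, prot, geometry, gastric, intestinal)
  state <- .integrate_transit(drug, form, prot, fc)

  t_full <- fc$tg[seq(1, length(fc$tg), by = 2)]
  i_half <- seq(1, length(fc$tg), by = 2)
  samp <- prot$sampling_min
  interp <- function(y) stats::approx(t_full, y, xout = samp)$y
  dose <- form$dose_mg
  out <- tibble::tibble(
    time_min = samp,
    dissolved_pct = pmax(interp(state[, 3]), 0) / dose * 100,
    permeated_pct = pmax(interp(state[, 4]), 0) / dose * 100,
    solid_pct = pmax(interp(state[, 1] + state[, 2]), 0) / dose * 100,
    pH = interp(fc$ph[i_half]),
    volume_mL = interp(fc$volume[i_half])
  )
  class(out) <- c("profile_set", class(out))
  attr(out, "drug") <- drug
  attr(out, "formulation") <- form
  attr(out, "protocol") <- prot
  attr(out, "geometry") <- geometry
  attr(out, "dose_mg") <- dose
  out
}

#' Correct a sampled concentration series for withdrawn volume
#'
#' On the bench each sample withdraws `sample_volume_ml` of donor fluid
#' (replaced with fresh medium), so the cumulative dissolved amount at the
#' n-th sample is `C_n V_n + sum_{i<n} C_i v_s`. With `sample_volume_ml =
#' 0` this reduces to the instantaneous amount `C_n V_n`.
#'
#' @param conc_mg_ml concentration at each sampling time (mg/mL).
#' @param volume_ml donor volume at each sampling time (mL).
#' @param sample_volume_ml volume withdrawn per sample (mL), `>= 0`.
#' @param dose_mg dose (mg) for expressing the result as % of dose.
#' @return cumulative dissolved amount as % of dose.
#' @export
#' @examples
#' apply_sampling_correction(rep(0.1, 3), rep(100, 3), 1, 10) # third = 102%
apply_sampling_correction <- function(conc_mg_ml, volume_ml, sample_volume_ml,
                                      dose_mg) {
  stopifnot(
    length(conc_mg_ml) == length(volume_ml),
    sample_volume_ml >= 0, dose_mg > 0
  )
  removed <- dplyr::lag(cumsum(conc_mg_ml * sample_volume_ml), default = 0)
  (conc_mg_ml * volume_ml + removed) / dose_mg * 100
}

#' Plot dissolution and permeation profiles
#'
#' @param object a `profile_set` from [simulate_transit()].
#' @param ... unused.
#' @return A ggplot with dissolved and permeated % of dose versus time.
#' @method autoplot profile_set
#' @export
autoplot.profile_set <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time_min", "dissolved_pct", "permeated_pct")],
    -"time_min",
    names_to = "quantity", values_to = "pct"
  )
  long$quantity <- sub("_pct$", "", long$quantity)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$pct)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "% of dose") +
    ggplot2::theme_minimal()
}
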