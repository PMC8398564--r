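KW <- 1e-14

# mean number of protons removed per formula unit of a polyprotic acid with
# dissociation constants ka (ascending pKa), vectorized over h ([H+], M)
.nbar_removed <- function(h, pkas) {
  if (length(pkas) == 0) {
    return(rep(0, length(h)))
  }
  ka <- 10^(-pkas)
  beta <- cumprod(ka) # beta_j = K1*...*Kj
  num <- rep(0, length(h))
  den <- rep(1, length(h))
  hj <- rep(1, length(h))
  for (j in seq_along(beta)) {
    hj <- hj * h # h^j
    term <- beta[j] / hj
    num <- num + j * term
    den <- den + term
  }
  num / den
}

# Charge-balance residual (M) at given pH for a totals matrix.
# rows of `totals_mm` = independent compositions, columns = species in the
# order of `constants`; `offset_mm` and `ph` are parallel vectors.
.charge_residual <- function(ph, totals_mm, offset_mm, constants) {
  h <- 10^(-ph)
  oh <- KW / h
  tot <- totals_mm / 1000 # M
  fixed <- as.numeric(tot %*% (constants$na_per - constants$cl_per - constants$fixed_anion_per))
  buffer_neg <- rep(0, length(ph))
  for (k in seq_len(nrow(constants))) {
    pk <- constants$pkas[[k]]
    if (length(pk) > 0) {
      ck <- tot[, k]
      if (any(ck > 0)) {
        buffer_neg <- buffer_neg + ck * .nbar_removed(h, pk)
      }
    }
  }
  h - oh + offset_mm / 1000 + fixed - buffer_neg
}

# Vectorized bisection on pH in [0, 14]; 60 fixed iterations (interval
# ~1e-16 pH units), deterministic and derivative-free.
.solve_ph_many <- function(totals_mm, offset_mm, constants) {
  n <- nrow(totals_mm)
  lo <- rep(0, n)
  hi <- rep(14, n)
  r_lo <- .charge_residual(lo, totals_mm, offset_mm, constants)
  r_hi <- .charge_residual(hi, totals_mm, offset_mm, constants)
  if (any(r_lo < 0) || any(r_hi > 0)) {
    rlang::abort("pH solver: no sign change of the charge balance over [0, 14]; malformed composition")
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    r_mid <- .charge_residual(mid, totals_mm, offset_mm, constants)
    pos <- r_mid > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Solve the pH of a fluid composition by polyprotic charge balance
#'
#' Finds the unique pH in \[0, 14\] at which the charge balance
#' (fixed cations + H+ + strong-ion offset - fixed anions - OH- -
#' deprotonated buffer charge) is zero, by bisection. Concentrations are
#' treated as activities (no ionic-strength correction), which is adequate
#' at recipe-level accuracy.
#'
#' @param comp a [fluid_composition()].
#' @return pH (scalar).
#' @export
#' @examples
#' solve_ph(fluid_composition()) # pure water, 7
#' solve_ph(fluid_composition(strong_ion_offset_mm = -1)) # 1 mM strong acid, ~3
solve_ph <- function(comp) {
  stopifnot(inherits(comp, "fluid_composition"))
  .solve_ph_many(
    matrix(comp$species_totals_mm, nrow = 1),
    comp$strong_ion_offset_mm,
    comp$constants
  )
}

#' Strong-ion offset needed to reach a target pH
#'
#' The charge balance is linear in the strong-ion offset, so the adjustment
#' that reproduces the bench titration ("adjust with dilute HCl and/or
#' NaOH") has a closed form: minus the charge-balance residual of the
#' un-adjusted composition evaluated at the target pH.
#'
#' @param comp a [fluid_composition()] (its current offset is ignored).
#' @param target_ph desired pH in \[0, 14\].
#' @return offset in mM such that `solve_ph()` on the adjusted composition
#'   returns `target_ph`; monotone increasing in `target_ph`.
#' @export
#' @examples
#' calibrate_strong_ion(fluid_composition(), 1.6) # ~ -25.1 mM strong acid
calibrate_strong_ion <- function(comp, target_ph) {
  stopifnot(inherits(comp, "fluid_composition"))
  stopifnot(is.numeric(target_ph), length(target_ph) == 1, target_ph >= 0, target_ph <= 14)
  r0 <- .charge_residual(
    target_ph, matrix(comp$species_totals_mm, nrow = 1),
    0, comp$constants
  )
  -r0 * 1000
}

#' pH and composition trajectory during infusate mixing
#'
#' Evaluates the well-mixed state of a [mixing_schedule()] at each requested
#' time and solves the charge balance for pH, giving the gradual gastric to
#' intestinal pH shift driven by constant-rate infusion. Species amounts and
#' the strong-ion offset mix volume-weighted; pH is recomputed from the
#' mixed totals at every time.
#'
#' @param schedule a [mixing_schedule()]; time 0 is the start of infusion.
#' @param times sorted, non-negative times (min).
#' @return A tibble of class `ph_trajectory` with columns `time_min`,
#'   `volume_mL`, `pH`, `chloride_mM`, `strong_ion_offset_mM`, and one
#'   column per species (mM).
#' @export
ph_trajectory <- function(schedule, times) {
  stopifnot(inherits(schedule, "mixing_schedule"))
  stopifnot(is.numeric(times), all(times >= 0), !is.unsorted(times))
  constants <- schedule$initial_fluid$constants
  st <- .mixing_state_many(schedule, times)
  ph <- .solve_ph_many(st$totals_mm, st$offset_mm, constants)
  cl <- as.numeric(st$totals_mm %*% constants$cl_per) + pmax(0, -st$offset_mm)
  out <- tibble::tibble(
    time_min = times,
    volume_mL = st$volume_ml,
    pH = ph,
    chloride_mM = cl,
    strong_ion_offset_mM = st$offset_mm
  )
  sp <- tibble::as_tibble(st$totals_mm)
  names(sp) <- constants$species
  out <- dplyr::bind_cols(out, sp)
  class(out) <- c("ph_trajectory", class(out))
  out
}

#' Plot a pH trajectory
#'
#' @param object a `ph_trajectory` tibble from [ph_trajectory()].
#' @param ... unused.
#' @return A ggplot object showing pH versus time.
#' @method autoplot ph_trajectory
#' @export
autoplot.ph_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$pH)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (min)", y = "donor pH") +
    ggplot2::theme_minimal()
}
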