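#' Acid-base species registry for biorelevant media
#'
#' Returns the table of chemical species that may appear in a
#' [fluid_composition()], with the stoichiometric counts used in the charge
#' balance and the acid dissociation constants used for speciation.
#'
#' Each row describes one *analytical* species as weighed into the medium:
#' sodium salts contribute their sodium as a fixed cation while the parent
#' acid (phosphoric for Na2HPO4, carbonic for NaHCO3) is speciated from its
#' fully protonated form, so the "pre-removed" protons of the salt are
#' accounted for automatically by the sodium count. Taurocholate is treated
#' as a fully dissociated 1:1 sodium salt (an electroneutral spectator);
#' lecithin, d-glucose and the balanced-salt carrier background are neutral.
#'
#' Default dissociation constants (25 C, concentration scale, activity
#' corrections ignored): citric acid 3.13/4.76/6.40; phosphoric acid
#' 2.15/7.20/12.35; carbonic acid 6.35 (closed system, second dissociation
#' ignored below pH 9); HEPES 7.55 (single relevant dissociation).
#'
#' @param overrides optional named list mapping a species name to a numeric
#'   vector of replacement pKa values, e.g. `list(hepes = 7.48)`.
#' @return A tibble with columns `species`, `na_per` (Na+ equivalents per
#'   formula unit), `cl_per` (Cl- equivalents), `fixed_anion_per` (permanent
#'   -1 charges, e.g. taurocholate), and `pkas` (list column of acid pKas of
#'   the fully protonated parent, ascending).
#' @export
#' @examples
#' species_table()
species_table <- function(overrides = NULL) {
  tab <- tibble::tibble(
    species = c(
      "sodium_taurocholate", "lecithin", "nacl", "na2hpo4",
      "citric_acid", "nahco3", "d_glucose", "hepes", "hbss_background"
    ),
    na_per = c(1, 0, 1, 2, 0, 1, 0, 0, 0),
    cl_per = c(0, 0, 1, 0, 0, 0, 0, 0, 0),
    fixed_anion_per = c(1, 0, 0, 0, 0, 0, 0, 0, 0),
    pkas = list(
      numeric(0), numeric(0), numeric(0),
      c(2.15, 7.20, 12.35),
      c(3.13, 4.76, 6.40),
      6.35,
      numeric(0),
      7.55,
      numeric(0)
    )
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), rlang::is_named(overrides))
    bad <- setdiff(names(overrides), tab$species)
    if (length(bad) > 0) {
      rlang::abort(paste0("unknown species in overrides: ", paste(bad, collapse = ", ")))
    }
    for (nm in names(overrides)) {
      tab$pkas[[match(nm, tab$species)]] <- sort(as.numeric(overrides[[nm]]))
    }
  }
  tab
}

#' Construct a fluid composition
#'
#' The chemical identity of a chamber fluid: total analytical concentrations
#' of the registered species plus a signed strong-ion offset representing the
#' net strong base (positive) or strong acid (negative) added during pH
#' adjustment (the "diluted HCl and/or NaOH" of the bench recipe, whose exact
#' identity and amount are not part of the recipe).
#'
#' @param species named numeric vector of total concentrations in mM; names
#'   must appear in [species_table()]. Missing species are taken as 0.
#' @param strong_ion_offset_mm signed strong-ion concentration in mM
#'   (positive = strong base such as NaOH, negative = strong acid such as
#'   HCl). A negative offset contributes chloride in [chloride_mM()].
#' @param label free-text label.
#' @param constants species registry as returned by [species_table()];
#'   override to change shipped dissociation constants.
#' @return An object of class `fluid_composition`.
#' @export
#' @examples
#' fluid_composition(c(nacl = 34.2, citric_acid = 10), label = "toy acid")
fluid_composition <- function(species = numeric(0), strong_ion_offset_mm = 0,
                              label = "", constants = species_table()) {
  species <- unlist(species)
  if (length(species) > 0) {
    stopifnot(rlang::is_named(species))
    bad <- setdiff(names(species), constants$species)
    if (length(bad) > 0) {
      rlang::abort(paste0("unknown species: ", paste(bad, collapse = ", ")))
    }
    if (any(!is.finite(species)) || any(species < 0)) {
      rlang::abort("species totals must be finite and >= 0")
    }
  }
  if (!is.finite(strong_ion_offset_mm)) {
    rlang::abort("strong_ion_offset_mm must be finite")
  }
  totals <- stats::setNames(rep(0, nrow(constants)), constants$species)
  totals[names(species)] <- as.numeric(species)
  structure(
    list(
      species_totals_mm = totals,
      strong_ion_offset_mm = as.numeric(strong_ion_offset_mm),
      label = label,
      constants = constants
    ),
    class = "fluid_composition"
  )
}

#' @export
print.fluid_composition <- function(x, ...) {
  cat("<fluid_composition>", if (nzchar(x$label)) x$label else "(unlabelled)", "\n")
  nz <- x$species_totals_mm[x$species_totals_mm > 0]
  if (length(nz) > 0) {
    for (nm in names(nz)) cat(sprintf("  %-20s %9.4f mM\n", nm, nz[[nm]]))
  }
  cat(sprintf("  %-20s %+9.4f mM\n", "strong-ion offset", x$strong_ion_offset_mm))
  invisible(x)
}

#' Tidy a fluid composition into a tibble
#'
#' @param x a `fluid_composition`.
#' @param ... unused.
#' @return A tibble with columns `species` and `conc_mM` (the strong-ion
#'   offset appears as species `"strong_ion_offset"`).
#' @method tidy fluid_composition
#' @export
tidy.fluid_composition <- function(x, ...) {
  tibble::tibble(
    species = c(names(x$species_totals_mm), "strong_ion_offset"),
    conc_mM = c(unname(x$species_totals_mm), x$strong_ion_offset_mm)
  )
}

#' Fasted-state simulated gastric fluid (FaSSGF) recipe
#'
#' Shipped recipe for the 40 mL initial gastric fluid: sodium taurocholate
#' 0.08 mM, lecithin 0.02 mM, NaCl 34.2 mM, Na2HPO4 20 mM, citric acid
#' 10 mM, in purified water. If `ph` is given, the strong-ion offset is
#' calibrated with [calibrate_strong_ion()] so [solve_ph()] returns `ph`;
#' the standard protocol uses 1.6, 3.0, 5.0 or 6.5.
#'
#' @param ph optional target pH for the adjustment step.
#' @param constants species registry, see [species_table()].
#' @return A `fluid_composition`.
#' @export
#' @examples
#' solve_ph(recipe_fassgf(ph = 1.6))
recipe_fassgf <- function(ph = NULL, constants = species_table()) {
  comp <- fluid_composition(
    c(
      sodium_taurocholate = 0.08, lecithin = 0.02, nacl = 34.2,
      na2hpo4 = 20, citric_acid = 10
    ),
    label = "FaSSGF", constants = constants
  )
  if (!is.null(ph)) {
    comp$strong_ion_offset_mm <- calibrate_strong_ion(comp, ph)
    comp$label <- sprintf("FaSSGF pH %.1f", ph)
  }
  comp
}

#' Fasted-state simulated intestinal fluid (FaSSIF) recipe
#'
#' Shipped recipe for the 100 mL final intestinal fluid: sodium taurocholate
#' 3 mM, lecithin 0.75 mM, NaCl 13.7 mM, Na2HPO4 20 mM, citric acid 10 mM,
#' NaHCO3 4.17 mM, d-glucose 25 mM, HEPES 10 mM, in a balanced-salt carrier.
#' The glucose figure is the analytical total: 5.55 mM weighed in plus
#' 19.45 mM contributed by the carrier. The carrier's remaining salts are an
#' electroneutral spectator (`hbss_background`).
#'
#' @inheritParams recipe_fassgf
#' @return A `fluid_composition`.
#' @export
recipe_fassif <- function(ph = 6.5, constants = species_table()) {
  comp <- fluid_composition(
    c(
      sodium_taurocholate = 3, lecithin = 0.75, nacl = 13.7,
      na2hpo4 = 20, citric_acid = 10, nahco3 = 4.17,
      d_glucose = 25, hepes = 10, hbss_background = 1
    ),
    label = "FaSSIF", constants = constants
  )
  if (!is.null(ph)) {
    comp$strong_ion_offset_mm <- calibrate_strong_ion(comp, ph)
    comp$label <- sprintf("FaSSIF pH %.1f", ph)
  }
  comp
}

#' Total chloride concentration of a composition
#'
#' Chloride from chloride-bearing salts plus the chloride implied by a
#' negative strong-ion offset (acidification with HCl). Used by the
#' common-ion solubility cap of hydrochloride-forming weak bases.
#'
#' @param comp a `fluid_composition`.
#' @return chloride in mM.
#' @export
chloride_mM <- function(comp) {
  stopifnot(inherits(comp, "fluid_composition"))
  cl <- sum(comp$species_totals_mm * comp$constants$cl_per)
  cl + max(0, -comp$strong_ion_offset_mm)
}
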