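#' Write / read a profiles CSV
#'
#' Profiles round-trip through CSV at full double precision (columns
#' `time_min`, `dissolved_pct`, `permeated_pct`, `solid_pct`, `pH`,
#' `volume_mL`), the exchange format shared by the simulator, the
#' similarity pipeline and hand-entered bench data.
#'
#' @param profile a `profile_set` tibble.
#' @param path file path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles`
#'   returns a `profile_set` tibble.
#' @export
write_profiles <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(profile), path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("time_min", "dissolved_pct", "permeated_pct") %in% names(out)))
  class(out) <- c("profile_set", class(out))
  out
}

#' Write / read a drug-and-formulation YAML configuration
#'
#' Serializes a fixture (drug substance plus formulation) to a
#' self-documenting YAML file with units embedded in the key names, and
#' reads it back.
#'
#' @param fixture list with `drug` and `formulation` (as from
#'   [make_fixture()]).
#' @param path file path.
#' @return `write_fixture_config` returns `path` invisibly;
#'   `read_fixture_config` returns a fixture list.
#' @export
write_fixture_config <- function(fixture, path) {
  d <- fixture$drug
  f <- fixture$formulation
  cfg <- list(
    drug = list(
      name = d$name,
      base_pkas = as.numeric(d$base_pkas),
      intrinsic_solubility_mg_ml = d$intrinsic_solubility_mg_ml,
      mol_weight_g_mol = d$mol_weight_g_mol,
      chloride_ksp = d$chloride_ksp,
      permeation_coefficient_cm_min = d$permeation_coefficient_cm_min,
      precipitation_rate_per_min = d$precipitation_rate_per_min
    ),
    formulation = list(
      label = f$label,
      dose_mg = f$dose_mg,
      role = f$role,
      k_ref_per_min = f$k_ref,
      rpm_exponent = f$rpm_exponent,
      disintegration_tau = lapply(seq_len(nrow(f$tau)), function(i) {
        as.list(f$tau[i, ])
      })
    ),
    provenance = fixture$provenance
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_fixture_config
#' @export
read_fixture_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("drug", "formulation")) {
    if (is.null(cfg[[key]])) {
      rlang::abort(paste0("fixture config: missing '", key, "' block"),
        class = "transitsim_config_error"
      )
    }
  }
  d <- cfg$drug
  f <- cfg$formulation
  tau <- dplyr::bind_rows(lapply(f$disintegration_tau, tibble::as_tibble))
  list(
    drug = drug_substance(
      name = d$name,
      base_pkas = as.numeric(unlist(d$base_pkas)),
      intrinsic_solubility_mg_ml = d$intrinsic_solubility_mg_ml,
      mol_weight_g_mol = d$mol_weight_g_mol,
      chloride_ksp = d$chloride_ksp,
      permeation_coefficient_cm_min = d$permeation_coefficient_cm_min,
      precipitation_rate_per_min = d$precipitation_rate_per_min
    ),
    formulation = formulation(
      label = f$label, dose_mg = f$dose_mg, tau = tau,
      k_ref = f$k_ref_per_min, rpm_exponent = f$rpm_exponent,
      role = f$role
    ),
    provenance = unlist(cfg$provenance)
  )
}

#' Run manifest for reproducibility
#'
#' Records stable hashes of the configuration objects, the seed, package
#' version, output paths and a timestamp. Two runs with identical
#' configurations and seed produce identical manifests apart from the
#' timestamp.
#'
#' @param ... named configuration objects to hash.
#' @param seed integer seed used for any randomness in the run.
#' @param outputs character vector of output file paths.
#' @return A tibble with columns `field`, `value`.
#' @export
run_manifest <- function(..., seed = NA_integer_, outputs = character(0)) {
  cfgs <- list(...)
  stopifnot(length(cfgs) == 0 || rlang::is_named(cfgs))
  hashes <- vapply(cfgs, rlang::hash, character(1))
  tibble::tibble(
    field = c(
      "package_version", "seed",
      if (length(hashes)) paste0("hash_", names(hashes)),
      if (length(outputs)) paste0("output_", seq_along(outputs)),
      "timestamp"
    ),
    value = c(
      as.character(utils::packageVersion("transitsim")),
      as.character(seed),
      unname(hashes),
      outputs,
      format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
}

#' End-to-end bioequivalence assessment of a formulation pair
#'
#' Chains the full pipeline: fluid design (gastric recipe calibrated to
#' the protocol's initial pH, infusate designed from the final recipe),
#' simulation of the reference and test products under the same protocol,
#' and the Ta-based f2 permeation comparison.
#'
#' @param reference,test fixture lists (`drug` + `formulation`), e.g. from
#'   [make_fixture()].
#' @param prot a [protocol()].
#' @param geometry a [device_geometry()].
#' @param border f2 similarity border.
#' @return list with `result` (a `similarity_result`),
#'   `reference_profile`, `test_profile` (`profile_set`s), `fluid_design`
#'   (the [design_fluid_report()] tibble) and `manifest`.
#' @export
#' @examples
#' \donttest{
#' pair <- run_be_assessment(
#'   make_fixture("naftopidil_ordinary"), make_fixture("naftopidil_od"),
#'   protocol(paddle_rpm = 100, water_disintegration = TRUE, step_min = 0.05)
#' )
#' glance(pair$result)
#' }
run_be_assessment <- function(reference, test, prot = protocol(),
                              geometry = device_geometry(), border = 50) {
  gastric <- recipe_fassgf(ph = prot$initial_gastric_ph)
  intestinal <- recipe_fassif(ph = prot$final_ph)
  design <- design_fluid_report(
    gastric, geometry$gastric_volume_ml,
    intestinal, geometry$final_volume_ml
  )
  ref_prof <- simulate_transit(reference$drug, reference$formulation, prot,
    geometry = geometry, gastric = gastric, intestinal = intestinal
  )
  test_prof <- simulate_transit(test$drug, test$formulation, prot,
    geometry = geometry, gastric = gastric, intestinal = intestinal
  )
  res <- compare_permeation(test_prof, ref_prof, border = border,
    at_min = max(prot$sampling_min)
  )
  list(
    result = res,
    reference_profile = ref_prof,
    test_profile = test_prof,
    fluid_design = design,
    manifest = run_manifest(
      protocol = prot, geometry = geometry,
      reference = reference, test = test
    )
  )
}
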