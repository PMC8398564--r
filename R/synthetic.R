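#' Build a scenario grid over gastrointestinal physiology
#'
#' Crossed factor levels of the device's physiological knobs: initial
#' gastric pH (1.6 healthy to 6.5 achlorhydric), paddle speed (agitation
#' strength), infusion time (gastric emptying surrogate), and the
#' water-pre-dispersion flag.
#'
#' @param gastric_ph subset of `c(1.6, 3.0, 5.0, 6.5)`.
#' @param rpm subset of `c(50, 100, 200)`.
#' @param infusion_min subset of `c(10, 20)`.
#' @param water_disintegration logical level(s).
#' @return A tibble with one row per scenario and a `scenario_id` column.
#' @export
#' @examples
#' scenario_grid(gastric_ph = c(1.6, 3.0), rpm = 100)
scenario_grid <- function(gastric_ph = c(1.6, 3.0, 5.0, 6.5),
                          rpm = c(50, 100, 200),
                          infusion_min = c(10, 20),
                          water_disintegration = FALSE) {
  stopifnot(
    length(gastric_ph) > 0, length(rpm) > 0, length(infusion_min) > 0,
    length(water_disintegration) > 0
  )
  g <- tidyr::expand_grid(
    gastric_ph = sort(unique(gastric_ph)),
    rpm = sort(unique(rpm)),
    infusion_min = sort(unique(infusion_min)),
    water_disintegration = unique(water_disintegration)
  )
  g$scenario_id <- sprintf(
    "pH%.1f_%drpm_%dmin%s",
    g$gastric_ph, as.integer(g$rpm), as.integer(g$infusion_min),
    ifelse(g$water_disintegration, "_water", "")
  )
  dplyr::relocate(g, "scenario_id")
}

#' Generate noisy replicate observations of a profile
#'
#' Emulates bench measurement of a simulated profile: multiplicative
#' lognormal noise with a given coefficient of variation applied
#' independently to every dissolved and permeated observation
#' (mean-preserving, so the replicate mean converges to the true profile),
#' and a lower quantification limit below which values are reported as
#' half the floor.
#'
#' @param profile a `profile_set` (or data frame with `time_min`,
#'   `dissolved_pct`, `permeated_pct`).
#' @param cv fractional coefficient of variation per observation, `>= 0`.
#' @param floor_pct lower quantification limit (% of dose); observations
#'   below it are reported as `floor_pct / 2`. Default 0 (disabled).
#' @param replicates number of replicates (3 emulates the bench design).
#' @param seed integer seed; fixed seed gives identical output.
#' @return A tibble with columns `replicate`, `time_min`,
#'   `dissolved_pct`, `permeated_pct`.
#' @export
generate_observed <- function(profile, cv = 0.1, floor_pct = 0,
                              replicates = 3, seed = 1) {
  stopifnot(cv >= 0, floor_pct >= 0, replicates >= 1)
  sdlog <- sqrt(log(1 + cv^2))
  noisy <- function(x, n) {
    if (cv == 0) {
      return(rep(x, n))
    }
    # meanlog = -sdlog^2/2 makes the multiplicative factor mean 1
    out <- rep(x, n) * stats::rlnorm(length(x) * n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    if (floor_pct > 0) out[out < floor_pct] <- floor_pct / 2
    out
  }
  withr::with_seed(seed, {
    nt <- nrow(profile)
    tibble::tibble(
      replicate = rep(seq_len(replicates), each = nt),
      time_min = rep(profile$time_min, replicates),
      dissolved_pct = noisy(profile$dissolved_pct, replicates),
      permeated_pct = noisy(profile$permeated_pct, replicates)
    )
  })
}

#' Run a scenario grid for a set of fixtures
#'
#' Simulates every fixture under every scenario of the grid and summarizes
#' each run (dissolved % at 30/60/120 min, permeated % at 120 min, maximum
#' dissolved %). When the fixture set contains both a reference-role and a
#' test-role product of the same drug (e.g. the ordinary and OD
#' formulations), the Ta-based f2 comparison is computed per scenario.
#'
#' @param grid a tibble from [scenario_grid()].
#' @param fixtures character vector of [make_fixture()] names, or a named
#'   list of fixture objects.
#' @param step_min integrator step passed to [protocol()].
#' @param sampling_min sampling schedule passed to [protocol()].
#' @return list with `runs` (one row per scenario x fixture; the full
#'   `profile_set` in the list-column `profile`) and `comparisons` (one
#'   row per scenario with `ta_min`, `f2`, `similar`; empty when no
#'   reference/test pairing exists).
#' @export
run_grid <- function(grid, fixtures,
                     step_min = 0.01,
                     sampling_min = c(0, 5, 10, 15, 20, 30, 45, 60, 90, 120)) {
  if (is.character(fixtures)) {
    fixtures <- stats::setNames(lapply(fixtures, make_fixture), fixtures)
  }
  stopifnot(length(fixtures) > 0, rlang::is_named(fixtures))
  runs <- tidyr::expand_grid(grid, fixture = names(fixtures))
  runs <- dplyr::rowwise(runs)
  runs <- dplyr::mutate(runs, profile = list({
    fx <- fixtures[[.data$fixture]]
    simulate_transit(
      fx$drug, fx$formulation,
      protocol(
        initial_gastric_ph = .data$gastric_ph,
        infusion_min = .data$infusion_min,
        paddle_rpm = .data$rpm,
        water_disintegration = .data$water_disintegration,
        step_min = step_min,
        sampling_min = sampling_min
      )
    )
  }))
  runs <- dplyr::ungroup(runs)
  at <- function(p, t) {
    v <- p$dissolved_pct[abs(p$time_min - t) < 1e-9]
    if (length(v) == 1) v else NA_real_
  }
  runs <- dplyr::mutate(runs,
    dissolved_30 = purrr::map_dbl(.data$profile, at, 30),
    dissolved_60 = purrr::map_dbl(.data$profile, at, 60),
    dissolved_120 = purrr::map_dbl(.data$profile, at, 120),
    max_dissolved = purrr::map_dbl(.data$profile, ~ max(.x$dissolved_pct)),
    permeated_120 = purrr::map_dbl(
      .data$profile,
      ~ .x$permeated_pct[abs(.x$time_min - 120) < 1e-9]
    )
  )

  roles <- purrr::map_chr(fixtures, ~ .x$formulation$role)
  comparisons <- tibble::tibble(
    scenario_id = character(0), ta_min = numeric(0),
    f2 = numeric(0), similar = logical(0)
  )
  if (any(roles == "reference") && any(roles == "test")) {
    ref_name <- names(fixtures)[roles == "reference"][1]
    test_name <- names(fixtures)[roles == "test"][1]
    comparisons <- purrr::map_dfr(unique(runs$scenario_id), function(sid) {
      ref <- runs$profile[runs$scenario_id == sid & runs$fixture == ref_name][[1]]
      tst <- runs$profile[runs$scenario_id == sid & runs$fixture == test_name][[1]]
      res <- compare_permeation(tst, ref)
      tibble::tibble(
        scenario_id = sid, ta_min = res$ta_min,
        f2 = res$f2, similar = res$similar
      )
    })
  }
  list(runs = runs, comparisons = comparisons)
}
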