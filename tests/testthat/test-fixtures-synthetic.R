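test_that("fixture definitions encode the intended physicochemistry", {
  met <- make_fixture("metoprolol_like")
  expect_length(met$drug$base_pkas, 0) # pH-independent
  # solubility never rate-limiting: saturation far above the full dose in 40 mL
  expect_gt(
    equilibrium_solubility(met$drug, 1.6) * 40,
    10 * met$formulation$dose_mg
  )

  ord <- make_fixture("naftopidil_ordinary")
  od <- make_fixture("naftopidil_od")
  # the two products share the drug substance (pKa 3.7/6.7) ...
  expect_identical(ord$drug, od$drug)
  expect_equal(ord$drug$base_pkas, c(6.7, 3.7))
  # ... and differ only in disintegration behaviour
  expect_false(identical(ord$formulation$tau, od$formulation$tau))
  tau_of <- function(fx, medium, rpm = 100) disintegration_tau(fx$formulation, medium, rpm)
  # OD: very fast in water, gel-inhibited in acidic chloride media
  expect_lt(tau_of(od, "water"), tau_of(od, "acidic_chloride"))
  # ordinary: the reverse ordering at standard agitation
  expect_gt(tau_of(ord, "water"), tau_of(ord, "acidic_chloride"))
  expect_error(make_fixture("unknown_drug"))
})

test_that("noise-free observation generation is the identity and seeds are reproducible", {
  fx <- make_fixture("metoprolol_like")
  prof <- simulate_transit(fx$drug, fx$formulation, fast_protocol())
  clean <- generate_observed(prof, cv = 0, replicates = 3, seed = 7)
  for (r in 1:3) {
    expect_equal(clean$dissolved_pct[clean$replicate == r], prof$dissolved_pct)
  }
  a <- generate_observed(prof, cv = 0.15, replicates = 3, seed = 11)
  b <- generate_observed(prof, cv = 0.15, replicates = 3, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_observed(prof, cv = 0.15, replicates = 3, seed = 12)))
})

test_that("replicate means converge to the true profile (mean-preserving noise)", {
  prof <- tibble::tibble(
    time_min = c(10, 30, 60, 120),
    dissolved_pct = c(20, 50, 80, 95),
    permeated_pct = c(0.5, 2, 5, 9)
  )
  obs <- generate_observed(prof, cv = 0.1, replicates = 1000, seed = 3)
  means <- dplyr::summarise(
    dplyr::group_by(obs, time_min),
    d = mean(dissolved_pct), p = mean(permeated_pct)
  )
  expect_equal(means$d, prof$dissolved_pct, tolerance = 0.01)
  expect_equal(means$p, prof$permeated_pct, tolerance = 0.01)
})

test_that("values below the quantification floor are reported as half the floor", {
  prof <- tibble::tibble(
    time_min = c(5, 120), dissolved_pct = c(0.01, 90), permeated_pct = c(0.001, 8)
  )
  obs <- generate_observed(prof, cv = 0.1, floor_pct = 0.5, replicates = 5, seed = 2)
  early <- obs[obs$time_min == 5, ]
  expect_true(all(early$dissolved_pct == 0.25))
  expect_true(all(early$permeated_pct == 0.25))
})

test_that("a singleton grid reproduces a direct simulation call", {
  grid <- scenario_grid(
    gastric_ph = 1.6, rpm = 200, infusion_min = 10,
    water_disintegration = FALSE
  )
  expect_equal(nrow(grid), 1)
  res <- run_grid(grid, "dipyridamole_like", step_min = 0.05)
  fx <- make_fixture("dipyridamole_like")
  direct <- simulate_transit(fx$drug, fx$formulation, fast_protocol(paddle_rpm = 200))
  expect_equal(res$runs$profile[[1]]$dissolved_pct, direct$dissolved_pct)
  expect_equal(res$runs$max_dissolved, max(direct$dissolved_pct))
  expect_equal(nrow(res$comparisons), 0) # no reference/test pairing
})

test_that("permeation falls monotonically with initial gastric pH for the weak base", {
  grid <- scenario_grid(
    gastric_ph = c(1.6, 3.0, 5.0, 6.5), rpm = 100, infusion_min = 20,
    water_disintegration = FALSE
  )
  res <- run_grid(grid, "dipyridamole_like", step_min = 0.02)
  runs <- dplyr::arrange(res$runs, gastric_ph)
  expect_true(all(diff(runs$permeated_120) < 0))
  expect_true(all(diff(runs$max_dissolved) < 0))
})

test_that("grid runs with a reference/test pairing report per-scenario f2", {
  grid <- scenario_grid(
    gastric_ph = 1.6, rpm = c(50, 100), infusion_min = 10,
    water_disintegration = TRUE
  )
  res <- run_grid(grid, c("naftopidil_ordinary", "naftopidil_od"), step_min = 0.05)
  expect_equal(nrow(res$comparisons), 2)
  f2_100 <- res$comparisons$f2[grepl("100rpm", res$comparisons$scenario_id)]
  f2_50 <- res$comparisons$f2[grepl("_50rpm", res$comparisons$scenario_id)]
  expect_gt(f2_100, f2_50) # agitation-dependent similarity ordering
  # grid determinism: identical configs give identical tables
  res2 <- run_grid(grid, c("naftopidil_ordinary", "naftopidil_od"), step_min = 0.05)
  expect_equal(res$comparisons, res2$comparisons)
})
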