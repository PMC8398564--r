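test_that("an exactly identified one-parameter fit drives the residual to zero", {
  fit <- calibrate_fixture(
    c(y10 = exp(-0.3 * 10)),
    c(rate = 0.1),
    function(p) c(y10 = exp(-p[["rate"]] * 10))
  )
  expect_lt(abs(fit$residuals), 1e-6)
  expect_equal(unname(fit$par[["rate"]]), 0.3, tolerance = 1e-4)
})

test_that("calibration is deterministic for a fixed start", {
  target <- c(a = 2.5, b = 0.4)
  evalf <- function(p) c(a = p[["x"]] * p[["y"]], b = p[["x"]] / (1 + p[["y"]]))
  f1 <- calibrate_fixture(target, c(x = 1, y = 1), evalf)
  f2 <- calibrate_fixture(target, c(x = 1, y = 1), evalf)
  expect_identical(f1$par, f2$par)
})

test_that("dissolution and permeation constants are recoverable from clean profiles", {
  fx <- make_fixture("metoprolol_like")
  true_k <- fx$formulation$k_ref
  true_p <- fx$drug$permeation_coefficient_cm_min
  times <- c(10, 20, 30, 45, 60, 120)
  features_of <- function(k_ref, p_coef) {
    d <- fx$drug
    d$permeation_coefficient_cm_min <- p_coef
    f <- fx$formulation
    f$k_ref <- k_ref
    prof <- simulate_transit(d, f, protocol(step_min = 0.05, sampling_min = times))
    c(
      stats::setNames(prof$dissolved_pct[1:4], paste0("d", times[1:4])),
      stats::setNames(prof$permeated_pct[5:6], paste0("p", times[5:6]))
    )
  }
  truth <- features_of(true_k, true_p)
  # noise-free "observations" of the true profiles
  prof_true <- simulate_transit(fx$drug, fx$formulation, protocol(step_min = 0.05, sampling_min = times))
  obs <- generate_observed(prof_true, cv = 0, replicates = 1, seed = 1)
  expect_equal(
    unname(truth[1:4]), obs$dissolved_pct[match(times[1:4], obs$time_min)],
    tolerance = 1e-12
  )
  fit <- calibrate_fixture(
    truth,
    c(k_ref = true_k * 1.6, p_coef = true_p * 0.6),
    function(p) features_of(p[["k_ref"]], p[["p_coef"]]),
    maxit = 300
  )
  expect_equal(unname(fit$par[["k_ref"]]), true_k, tolerance = 0.05)
  expect_equal(unname(fit$par[["p_coef"]]), true_p, tolerance = 0.05)
})

test_that("recovery from noisy triplicate means stays within a realistic band", {
  fx <- make_fixture("metoprolol_like")
  true_k <- fx$formulation$k_ref
  true_p <- fx$drug$permeation_coefficient_cm_min
  times <- c(10, 20, 30, 45, 60, 120)
  features_of <- function(k_ref, p_coef) {
    d <- fx$drug
    d$permeation_coefficient_cm_min <- p_coef
    f <- fx$formulation
    f$k_ref <- k_ref
    prof <- simulate_transit(d, f, protocol(step_min = 0.05, sampling_min = times))
    c(
      stats::setNames(prof$dissolved_pct[1:4], paste0("d", times[1:4])),
      stats::setNames(prof$permeated_pct[5:6], paste0("p", times[5:6]))
    )
  }
  prof_true <- simulate_transit(fx$drug, fx$formulation, protocol(step_min = 0.05, sampling_min = times))
  obs <- generate_observed(prof_true, cv = 0.1, replicates = 3, seed = 17)
  means <- dplyr::summarise(dplyr::group_by(obs, time_min),
    d = mean(dissolved_pct), p = mean(permeated_pct)
  )
  target <- c(
    stats::setNames(means$d[match(times[1:4], means$time_min)], paste0("d", times[1:4])),
    stats::setNames(means$p[match(times[5:6], means$time_min)], paste0("p", times[5:6]))
  )
  fit <- calibrate_fixture(
    target,
    c(k_ref = true_k * 1.5, p_coef = true_p * 0.7),
    function(p) features_of(p[["k_ref"]], p[["p_coef"]]),
    maxit = 300
  )
  expect_equal(unname(fit$par[["k_ref"]]), true_k, tolerance = 0.25)
  expect_equal(unname(fit$par[["p_coef"]]), true_p, tolerance = 0.25)
})
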