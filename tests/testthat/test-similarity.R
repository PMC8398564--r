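make_profile <- function(times, permeated) {
  structure(
    tibble::tibble(time_min = times, permeated_pct = permeated),
    class = c("profile_set", class(tibble::tibble()))
  )
}

test_that("normalization is anchored to the reference 120-min value", {
  tt <- c(0, 30, 60, 90, 120)
  ref <- make_profile(tt, c(0, 2, 5, 7, 8))
  tst <- make_profile(tt, c(0, 1.5, 4, 5, 6))
  norm <- normalize_profile(tst, ref)
  expect_equal(norm$reference[5], 100)
  expect_equal(norm$test[5], 75) # 6 / 8 * 100
  # identical profiles normalize identically
  same <- normalize_profile(ref, ref)
  expect_equal(same$test, same$reference)
})

test_that("normalization rejects mismatched grids and zero references", {
  tt <- c(0, 60, 120)
  ref <- make_profile(tt, c(0, 4, 8))
  expect_error(
    normalize_profile(make_profile(c(0, 50, 120), c(0, 4, 8)), ref),
    class = "transitsim_grid_mismatch"
  )
  expect_error(
    normalize_profile(ref, make_profile(c(0, 60, 119), c(0, 4, 8))),
    class = "transitsim_grid_mismatch"
  )
  expect_error(
    normalize_profile(ref, make_profile(tt, c(0, 0, 0))),
    class = "transitsim_zero_reference"
  )
})

test_that("Ta selection picks the sampled value nearest 85% with earlier-time ties", {
  tt <- c(15, 30, 45, 60, 90, 120)
  # exact hit at 60
  norm <- tibble::tibble(time_min = tt, reference = c(20, 45, 70, 85, 95, 100))
  sel <- select_ta(norm)
  expect_equal(sel$ta_min, 60)
  expect_equal(sel$eval_min, c(15, 30, 45, 60))
  # nearest-value rule: 88 at 60 beats 80 at 45
  norm2 <- tibble::tibble(time_min = tt, reference = c(20, 45, 80, 88, 95, 100))
  expect_equal(select_ta(norm2)$ta_min, 60)
  # tie: 80 at 45 and 90 at 60 are equally distant; earlier wins
  norm3 <- tibble::tibble(time_min = tt, reference = c(20, 45, 80, 90, 95, 100))
  expect_equal(select_ta(norm3)$ta_min, 45)
})

test_that("a reference that never exceeds 50% has no defined evaluation window", {
  norm <- tibble::tibble(time_min = c(30, 60, 120), reference = c(10, 20, 40))
  expect_error(select_ta(norm), class = "transitsim_flat_profile")
})

test_that("f2 matches closed-form values and its structural properties", {
  expect_equal(f2_similarity(rep(5, 4), rep(5, 4)), 100)
  expect_equal(f2_similarity(rep(10, 4), rep(20, 4)), 50 * log10(100 / sqrt(101)),
    tolerance = 1e-12
  )
  expect_equal(f2_similarity(rep(10, 4), rep(20, 4)), 49.89, tolerance = 1e-4)
  expect_equal(f2_similarity(rep(10, 4), rep(12, 4)), 50 * log10(100 / sqrt(5)),
    tolerance = 1e-12
  )
  expect_equal(f2_similarity(rep(10, 4), rep(12, 4)), 82.53, tolerance = 1e-4)
  # symmetry
  t1 <- c(10, 30, 60, 85)
  r1 <- c(12, 33, 57, 86)
  expect_equal(f2_similarity(t1, r1), f2_similarity(r1, t1))
  # adding the same constant to both series leaves f2 unchanged
  expect_equal(f2_similarity(t1 + 7, r1 + 7), f2_similarity(t1, r1))
  # scaling both by c > 1 strictly lowers f2 when the profiles differ
  expect_lt(f2_similarity(1.5 * t1, 1.5 * r1), f2_similarity(t1, r1))
  expect_error(f2_similarity(1:3, 1:4), "equal length")
})

test_that("the similarity call is inclusive at the border", {
  expect_true(assess_similarity(100))
  expect_true(assess_similarity(50))
  expect_false(assess_similarity(49.89))
  expect_true(assess_similarity(40, border = 35))
})

test_that("the pipeline result is self-consistent and tidies cleanly", {
  tt <- c(0, 15, 30, 45, 60, 90, 120)
  ref <- make_profile(tt, c(0, 1, 2.5, 4, 5.5, 7, 8))
  tst <- make_profile(tt, c(0, 0.6, 1.8, 3.2, 4.8, 6.5, 7.6))
  res <- compare_permeation(tst, ref)
  expect_s3_class(res, "similarity_result")
  expect_equal(res$n, 4)
  expect_equal(res$eval_min, res$ta_min * (1:4) / 4)
  # one-line recomputation from the stored values
  expect_equal(
    res$f2,
    50 * log10(100 / sqrt(1 + mean((res$t_values - res$r_values)^2))),
    tolerance = 1e-12
  )
  expect_identical(res$similar, res$f2 >= 50)
  td <- tidy(res)
  expect_equal(nrow(td), 4)
  expect_equal(td$difference, res$t_values - res$r_values)
  gl <- glance(res)
  expect_equal(gl$f2, res$f2)
  expect_equal(gl$ta_min, res$ta_min)
})
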