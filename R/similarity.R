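#' Normalize permeation profiles to the reference endpoint
#'
#' Both the test and the reference permeation series are expressed as a
#' percentage of the *reference* product's permeated amount at the run
#' endpoint (120 min standard), so the reference series ends at exactly
#' 100. Both profiles must share the same sampling grid, which must
#' include the normalization time.
#'
#' @param test,reference `profile_set` tibbles (or data frames with
#'   `time_min` and `permeated_pct`).
#' @param at_min normalization time (min), default 120.
#' @return A tibble with columns `time_min`, `reference`, `test`
#'   (normalized permeation, %).
#' @export
normalize_profile <- function(test, reference, at_min = 120) {
  if (!isTRUE(all.equal(test$time_min, reference$time_min))) {
    rlang::abort("test and reference profiles are on different sampling grids",
      class = "transitsim_grid_mismatch"
    )
  }
  i <- which(abs(reference$time_min - at_min) < 1e-9)
  if (length(i) != 1) {
    rlang::abort(sprintf("sampling grid must include the normalization time %g min", at_min),
      class = "transitsim_grid_mismatch"
    )
  }
  denom <- reference$permeated_pct[i]
  if (!is.finite(denom) || denom <= 0) {
    rlang::abort("reference permeated amount at the normalization time is not positive",
      class = "transitsim_zero_reference"
    )
  }
  tibble::tibble(
    time_min = reference$time_min,
    reference = reference$permeated_pct / denom * 100,
    test = test$permeated_pct / denom * 100
  )
}

#' Select the similarity evaluation window (Ta)
#'
#' `Ta` is the sampled time at which the normalized reference profile is
#' closest to 85% (ties broken toward the earlier time); the four f2
#' evaluation times are `Ta/4, Ta/2, 3Ta/4, Ta`. Values at evaluation
#' times that fall between samples are obtained later by linear
#' interpolation.
#'
#' @param normalized a tibble from [normalize_profile()] (columns
#'   `time_min` and `reference`).
#' @param target target normalized level (%), default 85.
#' @return list with `ta_min` and `eval_min` (length 4).
#' @section Errors: a flat-profile error is raised when the reference
#'   never exceeds 50% (the evaluation window is undefined and is
#'   reported rather than guessed).
#' @export
select_ta <- function(normalized, target = 85) {
  stopifnot(all(c("time_min", "reference") %in% names(normalized)))
  ref <- normalized$reference
  tt <- normalized$time_min
  if (max(ref) <= 50) {
    rlang::abort("reference profile never exceeds 50%: Ta undefined",
      class = "transitsim_flat_profile"
    )
  }
  keep <- tt > 0
  tt <- tt[keep]
  ref <- ref[keep]
  dist <- abs(ref - target)
  ta <- tt[which.min(dist)] # which.min takes the first (earliest) minimum
  list(ta_min = ta, eval_min = ta * c(1, 2, 3, 4) / 4)
}

#' f2 similarity factor
#'
#' `f2 = 50 log10(100 / sqrt(1 + mean((T - R)^2)))`: 100 for identical
#' profiles, decreasing as the profiles separate; a mean absolute
#' difference of 10 percentage points across the compared times gives
#' about 50, the conventional similarity border.
#'
#' @param t_values,r_values equal-length non-empty numeric vectors of test
#'   and reference values (%).
#' @return f2 (dimensionless, `<= 100`); symmetric in its arguments.
#' @export
#' @examples
#' f2_similarity(rep(10, 4), rep(20, 4)) # 49.89
f2_similarity <- function(t_values, r_values) {
  if (length(t_values) != length(r_values) || length(t_values) == 0) {
    rlang::abort("t_values and r_values must be non-empty and of equal length")
  }
  msd <- mean((t_values - r_values)^2)
  50 * log10(100 / sqrt(1 + msd))
}

#' Similarity call from an f2 value
#'
#' @param f2 f2 value (finite).
#' @param border similarity border, default 50; the call is inclusive
#'   (`f2 == border` is similar), matching the regulatory phrasing
#'   "f2 >= 50".
#' @return logical: similar?
#' @export
assess_similarity <- function(f2, border = 50) {
  stopifnot(is.finite(f2))
  f2 >= border
}

#' Compare two permeation profiles (full similarity pipeline)
#'
#' Chains normalization to the reference 120-min endpoint, Ta selection
#' near 85%, linear interpolation of both normalized series at
#' `Ta/4, Ta/2, 3Ta/4, Ta`, the f2 similarity factor, and the
#' similar/dissimilar call.
#'
#' @param test,reference `profile_set` tibbles from [simulate_transit()]
#'   (or measured profiles with the same columns).
#' @param border similarity border (default 50).
#' @param at_min normalization time (default 120).
#' @param target Ta target level (default 85).
#' @return An object of class `similarity_result`: list with `ta_min`,
#'   `eval_min`, `t_values`, `r_values`, `n`, `f2`, `similar`, `border`.
#' @export
compare_permeation <- function(test, reference, border = 50, at_min = 120,
                               target = 85) {
  norm <- normalize_profile(test, reference, at_min = at_min)
  sel <- select_ta(norm, target = target)
  tv <- stats::approx(norm$time_min, norm$test, xout = sel$eval_min)$y
  rv <- stats::approx(norm$time_min, norm$reference, xout = sel$eval_min)$y
  f2 <- f2_similarity(tv, rv)
  structure(
    list(
      ta_min = sel$ta_min, eval_min = sel$eval_min,
      t_values = tv, r_values = rv, n = length(tv),
      f2 = f2, similar = assess_similarity(f2, border), border = border,
      normalized = norm
    ),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("<similarity_result>\n")
  cat(sprintf("  Ta = %g min; evaluation times: %s min\n", x$ta_min,
              paste(signif(x$eval_min, 4), collapse = ", ")))
  cat(sprintf("  f2 = %.2f (border %g) -> %s\n", x$f2, x$border,
              if (x$similar) "SIMILAR" else "DISSIMILAR"))
  invisible(x)
}

#' Tidy a similarity result
#'
#' @param x a `similarity_result`.
#' @param ... unused.
#' @return A tibble with one row per evaluation time: `eval_min`,
#'   `reference`, `test`, `difference`.
#' @method tidy similarity_result
#' @export
tidy.similarity_result <- function(x, ...) {
  tibble::tibble(
    eval_min = x$eval_min,
    reference = x$r_values,
    test = x$t_values,
    difference = x$t_values - x$r_values
  )
}

#' One-row summary of a similarity result
#'
#' @param x a `similarity_result`.
#' @param ... unused.
#' @return A one-row tibble: `ta_min`, `n`, `f2`, `border`, `similar`.
#' @method glance similarity_result
#' @export
glance.similarity_result <- function(x, ...) {
  tibble::tibble(
    ta_min = x$ta_min, n = x$n, f2 = x$f2,
    border = x$border, similar = x$similar
  )
}

#' Plot a similarity comparison
#'
#' @param object a `similarity_result` from [compare_permeation()].
#' @param ... unused.
#' @return A ggplot of both normalized profiles with the four evaluation
#'   times marked.
#' @method autoplot similarity_result
#' @export
autoplot.similarity_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$normalized, -"time_min",
    names_to = "profile", values_to = "normalized_pct"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_min, y = .data$normalized_pct, colour = .data$profile
  )) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = object$eval_min, linetype = "dotted") +
    ggplot2::labs(
      x = "time (min)", y = "normalized permeation (%)",
      subtitle = sprintf("f2 = %.1f (%s)", object$f2,
                         if (object$similar) "similar" else "dissimilar")
    ) +
    ggplot2::theme_minimal()
}
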