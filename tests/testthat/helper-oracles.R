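# Independent brute-force oracles used across tests. These deliberately do
# not reuse the package's internal solver machinery: the pH oracle scans a
# log-spaced [H+] grid for the charge-balance sign change, computing the
# speciation directly from mole-fraction expressions.

# Charge-balance residual (M) computed from first principles for a
# composition described as a list of rows:
#   list(conc_mm =, na = , cl = , fixed_anion = , pkas = c(...))
oracle_residual <- function(h, rows, offset_mm) {
  res <- h - 1e-14 / h + offset_mm / 1000
  for (r in rows) {
    c_m <- r$conc_mm / 1000
    res <- res + c_m * (r$na - r$cl - r$fixed_anion)
    if (length(r$pkas) > 0) {
      # mole fractions of the j-times-deprotonated forms
      ka <- 10^(-r$pkas)
      terms <- c(1, cumprod(ka) / h^seq_along(ka))
      alpha <- terms / sum(terms)
      res <- res - c_m * sum((seq_along(terms) - 1) * alpha)
    }
  }
  res
}

# Scan 1e5 log-spaced [H+] points over pH [0, 14]; return the pH at the
# sign change of the residual (bracket midpoint).
oracle_ph_scan <- function(rows, offset_mm, n_grid = 1e5) {
  ph_grid <- seq(0, 14, length.out = n_grid)
  res <- vapply(10^(-ph_grid), oracle_residual, numeric(1), rows = rows, offset_mm = offset_mm)
  i <- which(res[-length(res)] > 0 & res[-1] <= 0)[1]
  stopifnot(!is.na(i))
  (ph_grid[i] + ph_grid[i + 1]) / 2
}

# Translate a fluid_composition into oracle rows using the registry
# stoichiometry (the registry numbers are inputs, not solver code).
oracle_rows <- function(comp) {
  tab <- comp$constants
  lapply(seq_len(nrow(tab)), function(k) {
    list(
      conc_mm = comp$species_totals_mm[[tab$species[k]]],
      na = tab$na_per[k], cl = tab$cl_per[k],
      fixed_anion = tab$fixed_anion_per[k], pkas = tab$pkas[[k]]
    )
  })
}

# Random plausible buffer composition for property tests.
random_composition <- function() {
  pool <- c(
    nacl = 50, na2hpo4 = 30, citric_acid = 20,
    nahco3 = 10, hepes = 15, sodium_taurocholate = 5
  )
  pick <- sample(names(pool), sample(2:5, 1))
  conc <- stats::runif(length(pick), 0.5, pool[pick])
  fluid_composition(
    stats::setNames(conc, pick),
    strong_ion_offset_mm = stats::runif(1, -40, 15)
  )
}

# Small fast protocol for unit tests (coarse step, short run).
fast_protocol <- function(...) {
  protocol(step_min = 0.05, ...)
}
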