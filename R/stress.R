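#' Simulate stress under an arbitrary strain history
#'
#' Boltzmann superposition for a generalized Maxwell material,
#' \eqn{\sigma(t) = \int_0^t G(t-s)\,\dot\varepsilon(s)\,ds}, with the strain
#' history taken piecewise linear between the supplied samples.  The first
#' sample is treated as an instantaneous step from zero strain, so a
#' constant history \eqn{\varepsilon_0} reproduces step-strain relaxation
#' \eqn{\sigma(t) = \varepsilon_0 G(t)}.
#'
#' Within each linear segment the superposition integral has a closed form,
#' so the per-mode stress is advanced by the exact recursion
#' \deqn{\sigma_i(t_{k+1}) = \sigma_i(t_k)e^{-\Delta t/\tau_i} +
#'   G_i r \tau_i (1 - e^{-\Delta t/\tau_i})}
#' with \eqn{r} the segment strain rate; no quadrature error is incurred and
#' the result is exactly linear in the strain history.
#'
#' @inheritParams complex_moduli
#' @param strain_history A data frame with columns `time_s` (strictly
#'   increasing, >= 0) and `strain` (dimensionless strain fraction, e.g.
#'   0.1 for 10%).
#' @return The `strain_history` tibble with a `stress_pa` column appended.
#' @examples
#' sp <- maxwell_spectrum(1000, 1)
#' hist <- tibble::tibble(time_s = c(0, 1), strain = c(0.1, 0.1))
#' simulate_stress(sp, hist) # stress at 1 s = 100 * exp(-1)
#' @export
simulate_stress <- function(spectrum, strain_history) {
  spectrum <- as_maxwell_spectrum(spectrum)
  check_columns(strain_history, c("time_s", "strain"), "`strain_history`")
  t <- strain_history$time_s
  eps <- strain_history$strain
  check_numeric_vector(t, "time_s", nonnegative = TRUE, min_length = 1L)
  check_strictly_increasing(t, "time_s")
  check_numeric_vector(eps, "strain", min_length = 1L)

  g <- spectrum$modulus_pa
  tau <- spectrum$tau_s
  n <- length(t)
  stress <- numeric(n)
  sigma_i <- g * eps[1]                 # instantaneous step at t[1]
  stress[1] <- sum(sigma_i)
  if (n > 1) {
    for (k in 2:n) {
      dt <- t[k] - t[k - 1L]
      r <- (eps[k] - eps[k - 1L]) / dt
      grow <- -expm1(-dt / tau)         # 1 - exp(-dt/tau), accurate for huge tau
      sigma_i <- sigma_i * (1 - grow) + g * r * tau * grow
      stress[k] <- sum(sigma_i)
    }
  }
  out <- as_tibble(strain_history)
  out$stress_pa <- stress
  out
}

#' Cycles until the peak stress of a cyclic loading series settles
#'
#' Splits a stress series into consecutive whole cycles, extracts the peak
#' absolute stress of each, and reports the first cycle whose peak differs
#' from the previous cycle's by less than `tolerance` (relative) and stays
#' within tolerance for every later cycle.  Used to quantify prestress
#' convergence of a pre-stretched viscoelastic patch under cyclic loading.
#'
#' @param stress A numeric vector of stresses (Pa), or a data frame with a
#'   `stress_pa` column such as the output of [simulate_stress()].  Trailing
#'   samples beyond the last whole cycle are ignored.
#' @param samples_per_cycle Number of samples making up one loading cycle.
#' @param tolerance Relative change in per-cycle peak stress below which two
#'   consecutive cycles count as converged (e.g. 0.01 for 1%).
#' @return A one-row tibble with columns `cycle` (the converged cycle index,
#'   1-based; equal to `n_cycles` when convergence was never reached),
#'   `converged` (logical) and `n_cycles` (whole cycles available).
#' @examples
#' sp <- maxwell_spectrum(1000, 1e9) # quasi-elastic: converges at cycle 2
#' t <- seq(0, 5, by = 0.01)
#' hist <- tibble::tibble(time_s = t, strain = 0.1 * sin(2 * pi * t))
#' cycles_to_convergence(simulate_stress(sp, hist), 100, 0.01)
#' @export
cycles_to_convergence <- function(stress, samples_per_cycle, tolerance) {
  if (is.data.frame(stress)) {
    check_columns(stress, "stress_pa", "`stress`")
    stress <- stress$stress_pa
  }
  check_numeric_vector(stress, "stress", min_length = 2L)
  check_number(samples_per_cycle, "samples_per_cycle", positive = TRUE)
  check_number(tolerance, "tolerance", positive = TRUE)
  samples_per_cycle <- as.integer(samples_per_cycle)
  n_cycles <- length(stress) %/% samples_per_cycle
  if (n_cycles < 2) {
    abort_domain("`stress` must contain at least 2 whole cycles.")
  }
  used <- stress[seq_len(n_cycles * samples_per_cycle)]
  peaks <- vapply(seq_len(n_cycles), function(k) {
    max(abs(used[((k - 1L) * samples_per_cycle + 1L):(k * samples_per_cycle)]))
  }, numeric(1))
  rel_change <- abs(diff(peaks)) / pmax(abs(peaks[-n_cycles]),
                                        .Machine$double.eps)
  ok <- rel_change < tolerance
  # first cycle k (>= 2) from which every later comparison stays converged
  stable_from <- NA_integer_
  if (any(ok)) {
    suffix_ok <- rev(cumprod(rev(ok))) == 1
    if (any(suffix_ok)) stable_from <- which(suffix_ok)[1] + 1L
  }
  if (is.na(stable_from)) {
    tibble(cycle = n_cycles, converged = FALSE, n_cycles = n_cycles)
  } else {
    tibble(cycle = stable_from, converged = TRUE, n_cycles = n_cycles)
  }
}
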