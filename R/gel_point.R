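#' Locate the gel point of an oscillatory frequency sweep
#'
#' The gel point is the frequency \eqn{f_{GP}} at which the storage modulus
#' G' equals the loss modulus G'', together with the common modulus value
#' \eqn{G'_{GP}} there.  Below \eqn{f_{GP}} the material responds
#' predominantly viscously, above it predominantly elastically; matching
#' \eqn{f_{GP}} to the heart rate is the design principle behind
#' heart-rate-matched patches.
#'
#' The crossover is located by linear interpolation of
#' \eqn{\log(G'/G'')} against \eqn{\log f} between the two samples that
#' bracket the sign change (rheometer sweeps are log-spaced, so log--log
#' interpolation is the natural local model).  The modulus is the common
#' value of the log-log interpolants of G' and G'' at that frequency.
#'
#' @param sweep A data frame with columns `frequency_hz` (strictly
#'   increasing, > 0), `g_prime_pa` and `g_double_prime_pa` (both > 0),
#'   e.g. from [complex_moduli()], [generate_sweep()] or [read_sweep_csv()].
#' @return A one-row tibble with columns `f_gp_hz` and `g_gp_pa`.
#' @section Errors:
#' If G' - G'' never changes sign a `gelstrain_no_crossover` error is
#' signalled.  If it changes sign more than once, a
#' `gelstrain_multiple_crossovers` error is signalled whose `brackets` field
#' lists every bracketing frequency pair; a silent pick would hide a
#' qualitatively unexpected material.
#' @examples
#' sweep <- complex_moduli(maxwell_spectrum(2000, 1 / (2 * pi)),
#'                         10^seq(log10(0.05), log10(20), length.out = 2001))
#' find_gel_point(sweep) # ~ (1 Hz, 1000 Pa)
#' @export
find_gel_point <- function(sweep) {
  check_columns(sweep, c("frequency_hz", "g_prime_pa", "g_double_prime_pa"),
                "`sweep`")
  f <- sweep$frequency_hz
  gp <- sweep$g_prime_pa
  gpp <- sweep$g_double_prime_pa
  check_numeric_vector(f, "frequency_hz", positive = TRUE, min_length = 2L)
  check_strictly_increasing(f, "frequency_hz")
  check_numeric_vector(gp, "g_prime_pa", positive = TRUE, min_length = 2L)
  check_numeric_vector(gpp, "g_double_prime_pa", positive = TRUE,
                       min_length = 2L)

  d <- log(gp) - log(gpp)
  n <- length(d)
  hits <- which(d == 0)                         # crossover at a sample
  bracket <- which(d[-n] * d[-1] < 0)           # strict sign change
  n_cross <- length(hits) + length(bracket)
  if (n_cross == 0) {
    abort_gelstrain(
      "G' and G'' do not cross within the sampled frequency range.",
      "gelstrain_no_crossover")
  }
  if (n_cross > 1) {
    brackets <- rbind(
      if (length(hits)) cbind(f[hits], f[hits]),
      if (length(bracket)) cbind(f[bracket], f[bracket + 1L]))
    abort_gelstrain(
      sprintf("G' - G'' changes sign %d times; expected a single crossover.",
              n_cross),
      "gelstrain_multiple_crossovers",
      brackets = brackets)
  }
  if (length(hits) == 1) {
    return(tibble(f_gp_hz = f[hits], g_gp_pa = gp[hits]))
  }
  i <- bracket
  lf <- log(f)
  t <- d[i] / (d[i] - d[i + 1L])
  lf_star <- lf[i] + t * (lf[i + 1L] - lf[i])
  lg_star <- log(gp[i]) + t * (log(gp[i + 1L]) - log(gp[i]))
  tibble(f_gp_hz = exp(lf_star), g_gp_pa = exp(lg_star))
}
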