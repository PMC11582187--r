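#' Build a generalized Maxwell (Prony series) relaxation spectrum
#'
#' A spectrum is a set of spring--dashpot modes, each with a shear-modulus
#' weight \eqn{G_i} (Pa) and a relaxation time \eqn{\tau_i} (s), representing
#' a dynamically crosslinked network as \eqn{G(t) = \sum_i G_i e^{-t/\tau_i}}.
#' Modes are stored in order of decreasing relaxation time.  No equilibrium
#' (infinite-time) mode is included: the networks modelled here are fully
#' dynamic and relax toward zero stress.
#'
#' @param modulus_pa Numeric vector of mode stiffnesses, Pa; all > 0.
#' @param tau_s Numeric vector of relaxation times, s; all > 0 and pairwise
#'   distinct (relative tolerance 1e-9).
#'
#' @return A tibble of class `maxwell_spectrum` with columns `modulus_pa`
#'   and `tau_s`, one row per mode, ordered by decreasing `tau_s`.
#' @examples
#' sp <- maxwell_spectrum(c(600, 400), c(1, 0.01))
#' total_modulus(sp)
#' @export
maxwell_spectrum <- function(modulus_pa, tau_s) {
  check_numeric_vector(modulus_pa, "modulus_pa", positive = TRUE)
  check_numeric_vector(tau_s, "tau_s", positive = TRUE)
  if (length(modulus_pa) != length(tau_s)) {
    abort_domain("`modulus_pa` and `tau_s` must have the same length.")
  }
  ord <- order(tau_s, decreasing = TRUE)
  tau_s <- tau_s[ord]
  modulus_pa <- modulus_pa[ord]
  if (length(tau_s) > 1) {
    rel_gap <- abs(diff(tau_s)) / tau_s[-length(tau_s)]
    if (any(rel_gap < 1e-9)) {
      abort_domain(
        "relaxation times must be pairwise distinct (relative 1e-9).")
    }
  }
  out <- tibble(modulus_pa = modulus_pa, tau_s = tau_s)
  class(out) <- c("maxwell_spectrum", class(out))
  out
}

#' @rdname maxwell_spectrum
#' @param spectrum A `maxwell_spectrum`.
#' @return `total_modulus()`: the instantaneous stiffness
#'   \eqn{G_0 = \sum_i G_i}, Pa.
#' @export
total_modulus <- function(spectrum) {
  spectrum <- as_maxwell_spectrum(spectrum)
  sum(spectrum$modulus_pa)
}

as_maxwell_spectrum <- function(x) {
  if (inherits(x, "maxwell_spectrum")) return(x)
  if (is.data.frame(x) && all(c("modulus_pa", "tau_s") %in% names(x))) {
    return(maxwell_spectrum(x$modulus_pa, x$tau_s))
  }
  abort_domain(
    "expected a `maxwell_spectrum` (or data frame with `modulus_pa`, `tau_s`).")
}

#' @export
print.maxwell_spectrum <- function(x, ...) {
  cat(sprintf("Maxwell spectrum: %d mode(s), G0 = %.6g Pa\n",
              nrow(x), sum(x$modulus_pa)))
  NextMethod()
}

#' Storage and loss moduli of a Maxwell spectrum
#'
#' Frequency response of the generalized Maxwell model under small-amplitude
#' oscillatory shear:
#' \deqn{G'(\omega) = \sum_i G_i \frac{(\omega\tau_i)^2}{1+(\omega\tau_i)^2},
#'   \quad
#'   G''(\omega) = \sum_i G_i \frac{\omega\tau_i}{1+(\omega\tau_i)^2}}
#' with \eqn{\omega = 2\pi f}.  Frequencies are user-facing in Hz; the angular
#' frequency is internal only.
#'
#' @param spectrum A [maxwell_spectrum()].
#' @param frequencies_hz Numeric vector of oscillation frequencies, Hz; all
#'   > 0.
#' @return A tibble (one row per frequency) with columns `frequency_hz`,
#'   `g_prime_pa` (storage modulus) and `g_double_prime_pa` (loss modulus).
#' @examples
#' complex_moduli(maxwell_spectrum(1000, 1), 1 / (2 * pi))
#' @export
complex_moduli <- function(spectrum, frequencies_hz) {
  spectrum <- as_maxwell_spectrum(spectrum)
  check_numeric_vector(frequencies_hz, "frequencies_hz", positive = TRUE)
  omega_tau <- outer(2 * pi * frequencies_hz, spectrum$tau_s)
  denom <- 1 + omega_tau^2
  gp <- drop((omega_tau^2 / denom) %*% spectrum$modulus_pa)
  gpp <- drop((omega_tau / denom) %*% spectrum$modulus_pa)
  tibble(frequency_hz = frequencies_hz,
         g_prime_pa = gp,
         g_double_prime_pa = gpp)
}

#' Relaxation modulus of a Maxwell spectrum
#'
#' Evaluates \eqn{G(t) = \sum_i G_i e^{-t/\tau_i}} at the requested times.
#'
#' @inheritParams complex_moduli
#' @param times_s Numeric vector of times, s; all >= 0.
#' @return Numeric vector of relaxation moduli, Pa; `G(0)` equals
#'   [total_modulus()] and the function decreases strictly with time.
#' @examples
#' relaxation_modulus(maxwell_spectrum(800, 2), 2) # 800 * exp(-1)
#' @export
relaxation_modulus <- function(spectrum, times_s) {
  spectrum <- as_maxwell_spectrum(spectrum)
  check_numeric_vector(times_s, "times_s", nonnegative = TRUE)
  drop(exp(-outer(times_s, 1 / spectrum$tau_s)) %*% spectrum$modulus_pa)
}
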