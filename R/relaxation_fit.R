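#' Fit a multi-mode Maxwell model to a stress-relaxation curve
#'
#' Least-squares fit of the Prony series
#' \eqn{G(t) = \sum_{i=1}^{n} G_i e^{-t/\tau_i}} to a measured relaxation
#' curve (step-strain relaxation modulus or stress divided by the step
#' amplitude).  The default `n_modes = 2` is the second-order model used for
#' dual-bond-population gels, where the two relaxation times track the
#' exchange kinetics of the fast and slow dynamic crosslinks.
#'
#' Optimization is Levenberg--Marquardt ([minpack.lm::nls.lm()]) on the log
#' of every parameter, which keeps all moduli and times positive without
#' explicit bounds.  Relaxation times are initialized log-spaced across the
#' observed time window and mode weights equally at \eqn{G(0)/n}: a robust
#' default for exponential sums, whose fitting is notoriously
#' initialization-sensitive.
#'
#' @param curve A data frame with columns `time_s` (strictly increasing,
#'   first value >= 0) and `modulus_pa` (> 0), with at least
#'   `2 * n_modes + 1` rows.
#' @param n_modes Number of Maxwell modes to fit (default 2).
#' @return An object of class `relaxation_fit`: a list with elements
#'   `spectrum` (a [maxwell_spectrum()]), `characteristic_time_s` (the
#'   weight-averaged time \eqn{\sum G_i\tau_i / \sum G_i}), `residual_norm`
#'   (root of the residual sum of squares, Pa), `fitted`, `data`, `n_modes`
#'   and `convergence`.  Supports [tidy()], [glance()], `predict()` and
#'   `print()`.
#' @section Errors:
#' Non-decaying input (constant or increasing trend) signals
#' `gelstrain_degenerate_relaxation`; failure of the optimizer signals
#' `gelstrain_fit_error` with the optimizer diagnostics attached.
#' @examples
#' sp <- maxwell_spectrum(c(800, 200), c(10, 0.5))
#' curve <- tibble::tibble(time_s = seq(0, 50, length.out = 200),
#'                         modulus_pa = relaxation_modulus(sp, seq(0, 50,
#'                           length.out = 200)))
#' fit <- fit_relaxation(curve)
#' tidy(fit)
#' glance(fit)
#' @export
fit_relaxation <- function(curve, n_modes = 2) {
  check_columns(curve, c("time_s", "modulus_pa"), "`curve`")
  check_number(n_modes, "n_modes", positive = TRUE)
  n_modes <- as.integer(n_modes)
  t <- curve$time_s
  y <- curve$modulus_pa
  check_numeric_vector(t, "time_s", nonnegative = TRUE,
                       min_length = 2L * n_modes + 1L)
  check_strictly_increasing(t, "time_s")
  check_numeric_vector(y, "modulus_pa", positive = TRUE)

  # decay over the observed window must be materially negative; a flat
  # trend whose least-squares slope is only rounding noise is degenerate
  slope <- coef(lm(y ~ t))[["t"]]
  if (slope * diff(range(t)) >= -1e-9 * mean(abs(y))) {
    abort_gelstrain(
      "relaxation data do not decay (constant or increasing trend).",
      "gelstrain_degenerate_relaxation")
  }

  tpos <- t[t > 0]
  tau0 <- if (n_modes == 1) {
    exp(mean(log(range(tpos))))
  } else {
    exp(seq(log(min(tpos)), log(max(tpos)), length.out = n_modes))
  }
  g0 <- rep(y[1] / n_modes, n_modes)
  par0 <- c(log(g0), log(tau0))

  residual_fn <- function(par) {
    g <- exp(par[seq_len(n_modes)])
    tau <- exp(par[n_modes + seq_len(n_modes)])
    drop(exp(-outer(t, 1 / tau)) %*% g) - y
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = residual_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 5000))
  if (!fit$info %in% 1:4) {
    abort_gelstrain(
      sprintf("relaxation fit did not converge: %s", fit$message),
      "gelstrain_fit_error", info = fit$info, optimizer_message = fit$message)
  }
  g_hat <- exp(fit$par[seq_len(n_modes)])
  tau_hat <- exp(fit$par[n_modes + seq_len(n_modes)])
  spectrum <- tryCatch(
    maxwell_spectrum(g_hat, tau_hat),
    gelstrain_domain_error = function(cnd) {
      abort_gelstrain(
        paste0("relaxation fit collapsed to a degenerate spectrum: ",
               rlang::cnd_message(cnd)),
        "gelstrain_fit_error")
    })
  fitted <- relaxation_modulus(spectrum, t)
  structure(
    list(
      spectrum = spectrum,
      characteristic_time_s =
        sum(spectrum$modulus_pa * spectrum$tau_s) / sum(spectrum$modulus_pa),
      residual_norm = sqrt(sum((fitted - y)^2)),
      fitted = fitted,
      data = tibble(time_s = t, modulus_pa = y),
      n_modes = n_modes,
      convergence = list(info = fit$info, message = fit$message,
                         iterations = fit$niter)),
    class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(
    "Maxwell relaxation fit: %d mode(s), G0 = %.6g Pa, tau_char = %.6g s\n",
    x$n_modes, total_modulus(x$spectrum), x$characteristic_time_s))
  cat(sprintf("residual norm %.4g Pa over %d samples\n",
              x$residual_norm, nrow(x$data)))
  print(tibble::as_tibble(x$spectrum))
  invisible(x)
}

#' @export
predict.relaxation_fit <- function(object, times_s = NULL, ...) {
  times_s <- times_s %||% object$data$time_s
  relaxation_modulus(object$spectrum, times_s)
}

#' Tidiers for Maxwell relaxation fits
#'
#' `tidy()` returns one row per fitted parameter (`g_1`, `tau_1`, ...,
#' ordered by decreasing relaxation time); `glance()` returns a one-row
#' model summary.
#'
#' @param x A `relaxation_fit` from [fit_relaxation()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy relaxation_fit
#' @export
tidy.relaxation_fit <- function(x, ...) {
  n <- nrow(x$spectrum)
  tibble(
    term = c(paste0("g_", seq_len(n)), paste0("tau_", seq_len(n))),
    estimate = c(x$spectrum$modulus_pa, x$spectrum$tau_s),
    unit = rep(c("Pa", "s"), each = n),
    mode = rep(seq_len(n), 2L))
}

#' @rdname tidy.relaxation_fit
#' @method glance relaxation_fit
#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble(
    n_modes = x$n_modes,
    g0_pa = total_modulus(x$spectrum),
    characteristic_time_s = x$characteristic_time_s,
    residual_norm = x$residual_norm,
    rmse = x$residual_norm / sqrt(nrow(x$data)),
    nobs = nrow(x$data),
    converged = x$convergence$info %in% 1:4)
}
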