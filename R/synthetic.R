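#' Simulate a noisy oscillatory frequency sweep
#'
#' Evaluates the analytic storage and loss moduli of a Maxwell spectrum on a
#' log-spaced frequency grid and applies independent multiplicative
#' lognormal noise with the requested coefficient of variation (lognormal
#' keeps simulated moduli positive, matching rheometer data).  The
#' emulated protocol is a small-strain sweep over roughly 0.1--10 Hz.
#'
#' @inheritParams complex_moduli
#' @param f_min_hz,f_max_hz Sweep frequency range, Hz; `0 < f_min < f_max`.
#' @param n_points Number of log-spaced frequencies (>= 2).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 returns the analytic moduli exactly).
#' @param seed Integer seed; generators are pure functions of their
#'   arguments and never touch the caller's RNG state.
#' @return A sweep tibble (`frequency_hz`, `g_prime_pa`,
#'   `g_double_prime_pa`).
#' @examples
#' generate_sweep(maxwell_spectrum(1000, 0.2), 0.1, 10, 25, 0.05, seed = 1)
#' @export
generate_sweep <- function(spectrum, f_min_hz = 0.1, f_max_hz = 10,
                           n_points = 40, noise_cv = 0, seed = 1) {
  check_number(f_min_hz, "f_min_hz", positive = TRUE)
  check_number(f_max_hz, "f_max_hz", positive = TRUE)
  if (f_min_hz >= f_max_hz) abort_domain("`f_min_hz` must be < `f_max_hz`.")
  check_number(n_points, "n_points", positive = TRUE)
  if (n_points < 2) abort_domain("`n_points` must be >= 2.")
  check_number(noise_cv, "noise_cv", nonnegative = TRUE)

  f <- exp(seq(log(f_min_hz), log(f_max_hz), length.out = as.integer(n_points)))
  sweep <- complex_moduli(spectrum, f)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- with_local_seed(seed, rlnorm(2L * nrow(sweep),
                                          meanlog = -sdlog^2 / 2,
                                          sdlog = sdlog))
    sweep$g_prime_pa <- sweep$g_prime_pa * noise[seq_len(nrow(sweep))]
    sweep$g_double_prime_pa <-
      sweep$g_double_prime_pa * noise[nrow(sweep) + seq_len(nrow(sweep))]
  }
  sweep
}

#' Simulate a noisy stress-relaxation curve
#'
#' Evaluates \eqn{G(t)} of a Maxwell spectrum on a linear time grid from 0
#' and applies multiplicative lognormal noise, emulating a step-strain
#' relaxation test recorded for tens of seconds.
#'
#' @inheritParams generate_sweep
#' @param t_max_s Final time, s (> 0).
#' @param n_points Number of samples on the linear grid from 0 to
#'   `t_max_s`; the default (2000 over 50 s) reflects a 40 Hz rheometer
#'   acquisition rate, dense enough that a sub-second fast mode remains
#'   statistically identifiable under percent-level noise.
#' @return A relaxation tibble (`time_s`, `modulus_pa`).
#' @examples
#' sp <- maxwell_spectrum(c(800, 200), c(10, 0.5))
#' generate_relaxation_curve(sp, 50, 100, 0.01, seed = 1)
#' @export
generate_relaxation_curve <- function(spectrum, t_max_s = 50,
                                      n_points = 2000, noise_cv = 0,
                                      seed = 1) {
  check_number(t_max_s, "t_max_s", positive = TRUE)
  check_number(n_points, "n_points", positive = TRUE)
  if (n_points < 2) abort_domain("`n_points` must be >= 2.")
  check_number(noise_cv, "noise_cv", nonnegative = TRUE)
  t <- seq(0, t_max_s, length.out = as.integer(n_points))
  g <- relaxation_modulus(spectrum, t)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    g <- g * with_local_seed(seed, rlnorm(length(g), meanlog = -sdlog^2 / 2,
                                          sdlog = sdlog))
  }
  tibble(time_s = t, modulus_pa = g)
}

#' Parameters of the beating-ventricle contour phantom
#'
#' Describes a mid-wall ring whose local radius follows
#' \eqn{r(\theta, t) = R\,(1 + \varepsilon(\theta)\, s(t) / 100)} with
#' \eqn{s(t)} a raised-cosine systolic pulse (0 at end-diastole, 1 at
#' end-systole) and \eqn{\varepsilon(\theta)} equal to
#' `infarct_peak_strain_pct` inside the infarct arc,
#' `healthy_peak_strain_pct` outside, cosine-smoothed over
#' `transition_width_deg` at each edge.  Because strain is imposed on the
#' radius, the circumferential strain of each angular sector equals the
#' radial scaling there, making segment-wise ground truth analytic.
#'
#' Defaults describe a rat-sized ventricle (mid-wall radius 3.5 mm, healthy
#' peak strain -20%, cycle period 0.25 s, i.e. a 4 Hz heart rate); the
#' `species = "pig"` preset scales to a porcine heart (25 mm, 0.8 s).
#'
#' @param diastolic_radius_mm Mid-wall radius at end-diastole, mm.
#' @param wall_thickness_mm Wall thickness, mm (metadata; the phantom is the
#'   mid-wall line).
#' @param n_frames Frames per cycle (>= 4; even values sample end-systole
#'   exactly).
#' @param healthy_peak_strain_pct Peak systolic strain of healthy wall,
#'   percent (negative = contraction).
#' @param infarct_peak_strain_pct Peak strain of the noncontractile infarct
#'   arc, percent (>= 0 = passive stretch).
#' @param infarct_span_deg Angular width of the infarct arc, degrees
#'   (0 <= span < 360; 0 disables the infarct).
#' @param transition_width_deg Angular width of the cosine-smoothed border
#'   transition at each infarct edge, degrees (>= 0).
#' @param point_noise_sd_mm Standard deviation of isotropic Gaussian noise
#'   added to every contour point coordinate, mm.
#' @param infarct_center_deg Angular position of the infarct arc centre,
#'   degrees counterclockwise from the x-axis.
#' @param n_points Contour points per frame.
#' @param period_s Cardiac cycle duration, s.
#' @param seed Integer seed for the point noise.
#' @param species `"rat"` (default) or `"pig"`; presets for radius, wall
#'   thickness and period, overridable by the explicit arguments.
#' @return A list of class `lv_phantom_spec`.
#' @examples
#' lv_phantom_spec()
#' lv_phantom_spec(species = "pig")
#' @export
lv_phantom_spec <- function(diastolic_radius_mm = NULL,
                            wall_thickness_mm = NULL,
                            n_frames = 20,
                            healthy_peak_strain_pct = -20,
                            infarct_peak_strain_pct = 5,
                            infarct_span_deg = 90,
                            transition_width_deg = 15,
                            point_noise_sd_mm = 0,
                            infarct_center_deg = 90,
                            n_points = 180,
                            period_s = NULL,
                            seed = 1,
                            species = c("rat", "pig")) {
  species <- match.arg(species)
  preset <- switch(species,
                   rat = list(radius = 3.5, wall = 2, period = 0.25),
                   pig = list(radius = 25, wall = 9, period = 0.8))
  diastolic_radius_mm <- diastolic_radius_mm %||% preset$radius
  wall_thickness_mm <- wall_thickness_mm %||% preset$wall
  period_s <- period_s %||% preset$period

  check_number(diastolic_radius_mm, "diastolic_radius_mm", positive = TRUE)
  check_number(wall_thickness_mm, "wall_thickness_mm", positive = TRUE)
  check_number(n_frames, "n_frames", positive = TRUE)
  if (n_frames < 4) abort_domain("`n_frames` must be >= 4.")
  check_number(healthy_peak_strain_pct, "healthy_peak_strain_pct")
  check_number(infarct_peak_strain_pct, "infarct_peak_strain_pct",
               nonnegative = TRUE)
  check_number(infarct_span_deg, "infarct_span_deg", nonnegative = TRUE)
  if (infarct_span_deg >= 360) {
    abort_domain("`infarct_span_deg` must be < 360.")
  }
  check_number(transition_width_deg, "transition_width_deg",
               nonnegative = TRUE)
  if (infarct_span_deg > 0 &&
      infarct_span_deg + 2 * transition_width_deg >= 360) {
    abort_domain(
      "infarct span plus both transitions must cover less than the full circumference.")
  }
  check_number(point_noise_sd_mm, "point_noise_sd_mm", nonnegative = TRUE)
  check_number(infarct_center_deg, "infarct_center_deg")
  check_number(n_points, "n_points", positive = TRUE)
  if (n_points < 24) abort_domain("`n_points` must be >= 24.")
  check_number(period_s, "period_s", positive = TRUE)
  check_number(seed, "seed", nonnegative = TRUE)

  structure(
    list(species = species,
         diastolic_radius_mm = diastolic_radius_mm,
         wall_thickness_mm = wall_thickness_mm,
         n_frames = as.integer(n_frames),
         healthy_peak_strain_pct = healthy_peak_strain_pct,
         infarct_peak_strain_pct = infarct_peak_strain_pct,
         infarct_span_deg = infarct_span_deg,
         transition_width_deg = transition_width_deg,
         point_noise_sd_mm = point_noise_sd_mm,
         infarct_center_deg = infarct_center_deg,
         n_points = as.integer(n_points),
         period_s = period_s,
         seed = as.integer(seed)),
    class = "lv_phantom_spec")
}

# Peak strain field epsilon(theta), percent, of a phantom (theta in radians,
# absolute frame).
phantom_strain_field <- function(spec) {
  hp <- spec$healthy_peak_strain_pct
  ip <- spec$infarct_peak_strain_pct
  centre <- spec$infarct_center_deg * pi / 180
  half <- spec$infarct_span_deg * pi / 360
  tw <- spec$transition_width_deg * pi / 180
  function(theta) {
    if (spec$infarct_span_deg == 0) return(rep(hp, length(theta)))
    delta <- abs(((theta - centre + pi) %% (2 * pi)) - pi)
    eps <- rep(hp, length(theta))
    eps[delta <= half] <- ip
    if (tw > 0) {
      ramp <- delta > half & delta < half + tw
      eps[ramp] <- hp + (ip - hp) *
        (1 + cos(pi * (delta[ramp] - half) / tw)) / 2
    }
    eps
  }
}

#' Generate a beating left-ventricle contour phantom with known truth
#'
#' Produces a cine contour table in the dialect consumed by
#' [analyze_cine()] together with the generator's ground truth: the true
#' per-segment peak circumferential strain (by dense quadrature of the
#' continuous phantom wall over each angular bin) and the boundary indices
#' at the two infarct edges.  Frame 0 is end-diastole; for even `n_frames`
#' the frame at half the cycle samples end-systole exactly.
#'
#' @param spec An [lv_phantom_spec()].
#' @param scheme A [segmentation_scheme()]; defines the bins the truth is
#'   integrated over.
#' @return A list with elements
#'   \describe{
#'     \item{`cine`}{tibble `frame_index` (0-based), `time_s`,
#'       `point_index`, `x_mm`, `y_mm`.}
#'     \item{`truth`}{list with `per_segment_peak_strain_pct` (tibble
#'       `segment_index`, `peak_strain_pct`), `border_boundaries`
#'       (0-based boundary indices at the infarct edges; empty when
#'       `infarct_span_deg == 0`), `end_diastole_frame`,
#'       `end_systole_frame`.}
#'   }
#' @examples
#' out <- generate_lv_cycle(lv_phantom_spec(n_frames = 8, seed = 7))
#' out$truth$border_boundaries
#' @export
generate_lv_cycle <- function(spec, scheme = segmentation_scheme()) {
  if (!inherits(spec, "lv_phantom_spec")) {
    abort_domain("`spec` must be an `lv_phantom_spec`.")
  }
  if (!inherits(scheme, "segmentation_scheme")) {
    abort_domain("`scheme` must be a `segmentation_scheme`.")
  }
  eps_fun <- phantom_strain_field(spec)
  R <- spec$diastolic_radius_mm
  nf <- spec$n_frames
  np <- spec$n_points
  theta <- 2 * pi * (seq_len(np) - 1L) / np
  eps_theta <- eps_fun(theta)
  s_pulse <- (1 - cos(2 * pi * (seq_len(nf) - 1L) / nf)) / 2

  noise <- if (spec$point_noise_sd_mm > 0) {
    with_local_seed(spec$seed,
                    rnorm(2L * np * nf, sd = spec$point_noise_sd_mm))
  } else {
    numeric(2L * np * nf)
  }

  cine <- purrr::map_dfr(seq_len(nf), function(j) {
    r <- R * (1 + eps_theta * s_pulse[j] / 100)
    off <- 2L * np * (j - 1L)
    tibble(frame_index = j - 1L,
           time_s = spec$period_s * (j - 1L) / nf,
           point_index = seq_len(np) - 1L,
           x_mm = r * cos(theta) + noise[off + seq_len(np)],
           y_mm = r * sin(theta) + noise[off + np + seq_len(np)])
  })

  n <- scheme$n_segments
  w <- 2 * pi / n
  # truth segment lengths by dense quadrature of the continuous wall
  m <- 100000L
  th_dense <- scheme$reference_angle + w * n * (seq_len(m) - 0.5) / m
  bin <- floor(((th_dense - scheme$reference_angle) %% (2 * pi)) / w) + 1L
  seg_len_at <- function(s) {
    r <- R * (1 + eps_fun(th_dense) * s / 100)
    # polyline quadrature: includes any radial jump at a sharp infarct edge
    x <- r * cos(th_dense)
    y <- r * sin(th_dense)
    dl <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
    as.numeric(tapply(dl, bin, sum))
  }
  len_dia <- seg_len_at(0)
  len_sys <- seg_len_at(1)
  truth_strain <- (len_sys - len_dia) / len_dia * 100

  border <- integer(0)
  if (spec$infarct_span_deg > 0) {
    centre <- spec$infarct_center_deg * pi / 180
    half <- spec$infarct_span_deg * pi / 360
    edges <- c(centre - half, centre + half)
    rel <- (edges - scheme$reference_angle) %% (2 * pi)
    border <- sort(unique((round(rel / w) - 1L) %% n))
  }

  list(
    cine = cine,
    truth = list(
      per_segment_peak_strain_pct = tibble(
        segment_index = seq_len(n) - 1L,
        peak_strain_pct = truth_strain),
      border_boundaries = border,
      end_diastole_frame = 0L,
      end_systole_frame = if (nf %% 2L == 0L) nf %/% 2L else
        which.min(abs(s_pulse - 1)) - 1L))
}
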