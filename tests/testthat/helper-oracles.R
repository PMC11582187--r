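# Independent brute-force oracles used to cross-check the implementations.
# These deliberately use different algorithms from the package code paths.

# Analytic moduli of a Maxwell spectrum, summed term by term with a loop
# (independent of the matrix evaluation in complex_moduli).
oracle_moduli <- function(modulus_pa, tau_s, f_hz) {
  gp <- 0
  gpp <- 0
  for (i in seq_along(modulus_pa)) {
    x <- 2 * pi * f_hz * tau_s[i]
    gp <- gp + modulus_pa[i] * x^2 / (1 + x^2)
    gpp <- gpp + modulus_pa[i] * x / (1 + x^2)
  }
  c(gp = gp, gpp = gpp)
}

# Crossover of the analytic G' - G'' by dense-grid bracketing followed by
# bisection on the analytic difference (no interpolation of sampled sweeps).
oracle_crossover <- function(spectrum, f_lo, f_hi, n_grid = 1e5) {
  diff_fn <- function(f) {
    m <- complex_moduli(spectrum, f)
    m$g_prime_pa - m$g_double_prime_pa
  }
  grid <- exp(seq(log(f_lo), log(f_hi), length.out = n_grid))
  d <- diff_fn(grid)
  s <- which(d[-n_grid] * d[-1] < 0)
  stopifnot(length(s) == 1)
  lo <- grid[s]
  hi <- grid[s + 1]
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    if (diff_fn(lo) * diff_fn(mid) <= 0) hi <- mid else lo <- mid
  }
  f_star <- sqrt(lo * hi)
  m <- complex_moduli(spectrum, f_star)
  c(f_gp_hz = f_star, g_gp_pa = (m$g_prime_pa + m$g_double_prime_pa) / 2)
}

# Boltzmann superposition by brute quadrature of
# sigma(t) = int_0^t G(t - s) deps/ds ds for a piecewise-linear strain
# history (plus the initial step), evaluated at a single time.  The strain
# rate is constant on each sampling segment, so the integral is quadratured
# segment by segment (trapezoid on G within each segment), which keeps the
# rate discontinuities off the quadrature nodes.
oracle_boltzmann <- function(spectrum, times_s, strains, t_eval,
                             n_sub = 200) {
  total <- strains[1] * relaxation_modulus(spectrum, t_eval - times_s[1])
  for (i in seq_len(length(times_s) - 1L)) {
    s0 <- times_s[i]
    s1 <- min(times_s[i + 1L], t_eval)
    if (s1 <= s0) break
    r <- (strains[i + 1L] - strains[i]) / (times_s[i + 1L] - times_s[i])
    s_grid <- seq(s0, s1, length.out = n_sub)
    g <- relaxation_modulus(spectrum, t_eval - s_grid)
    h <- s_grid[2] - s_grid[1]
    total <- total + r * h * (sum(g) - (g[1] + g[n_sub]) / 2)
  }
  total
}

# Per-cycle peak extraction with an explicit loop.
oracle_cycle_peaks <- function(stress, samples_per_cycle) {
  n_cycles <- length(stress) %/% samples_per_cycle
  peaks <- numeric(n_cycles)
  for (k in seq_len(n_cycles)) {
    idx <- ((k - 1) * samples_per_cycle + 1):(k * samples_per_cycle)
    peaks[k] <- max(abs(stress[idx]))
  }
  peaks
}

# Adjacent-segment differential via an explicit loop over all boundaries.
oracle_adjacent_diff <- function(strains) {
  n <- length(strains)
  out <- numeric(n)
  for (k in seq_len(n)) {
    out[k] <- abs(strains[k] - strains[if (k == n) 1 else k + 1])
  }
  out
}

# Per-sector arc length of a closed polyline by walking its edges and
# bisecting the angular crossing point on each boundary-straddling edge
# (bisection on the angle function, independent of the package's exact
# line-ray solve).  Assumes angles are monotone along the ring.
oracle_sector_lengths <- function(pts, centroid, ref_angle, n) {
  w <- 2 * pi / n
  rel_angle <- function(p) {
    (atan2(p[2] - centroid[2], p[1] - centroid[1]) - ref_angle) %% (2 * pi)
  }
  lengths <- numeric(n)
  m <- nrow(pts)
  for (e in seq_len(m)) {
    a <- pts[e, ]
    b <- pts[if (e == m) 1 else e + 1, ]
    el <- sqrt(sum((b - a)^2))
    ang_a <- rel_angle(a)
    ang_b <- rel_angle(b)
    span <- (ang_b - ang_a) %% (2 * pi)
    bins_crossed <- floor((ang_a + span) / w) - floor(ang_a / w)
    if (span > pi) stop("oracle assumes short edges")
    t_prev <- 0
    if (bins_crossed > 0) {
      for (bnd in (floor(ang_a / w) + 1):floor((ang_a + span) / w)) {
        target <- (bnd * w) %% (2 * pi)
        f <- function(t) {
          p <- a + t * (b - a)
          d <- (rel_angle(p) - target + pi) %% (2 * pi) - pi
          d
        }
        lo <- t_prev; hi <- 1
        if (f(lo) * f(hi) > 0) next
        for (i in 1:60) {
          mid <- (lo + hi) / 2
          if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
        }
        t_cross <- (lo + hi) / 2
        bin <- (floor(rel_angle(a + (t_prev + t_cross) / 2 * (b - a)) / w)
                %% n) + 1
        lengths[bin] <- lengths[bin] + (t_cross - t_prev) * el
        t_prev <- t_cross
      }
    }
    bin <- (floor(rel_angle(a + (t_prev + 1) / 2 * (b - a)) / w) %% n) + 1
    lengths[bin] <- lengths[bin] + (1 - t_prev) * el
  }
  lengths
}

# Circular distance between boundary indices.
circular_index_dist <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# Distance of the argmax-differential boundary from the nearest true border.
argmax_border_dist <- function(strain_map, truth, n = 24) {
  d <- strain_map$differentials
  am <- d$boundary_index[which.max(d$delta_epsilon_cc_pct)]
  min(circular_index_dist(am, truth$border_boundaries, n))
}

# Random in-hull formulation, given a seeded RNG stream.
random_formulation <- function() {
  formulation(runif(1, 15, 20), runif(1, 0.02, 0.98))
}

make_ring_df <- function(radius, n = 240, centre = c(0, 0), noise = 0) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(x_mm = centre[1] + radius * cos(theta) + rnorm(n, sd = noise),
             y_mm = centre[2] + radius * sin(theta) + rnorm(n, sd = noise))
}

make_cine_df <- function(radii, times = seq_along(radii) - 1, n = 120) {
  purrr::map_dfr(seq_along(radii), function(j) {
    theta <- 2 * pi * (seq_len(n) - 1) / n
    tibble::tibble(frame_index = j - 1, time_s = times[j],
                   point_index = seq_len(n) - 1,
                   x_mm = radii[j] * cos(theta),
                   y_mm = radii[j] * sin(theta))
  })
}
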