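# Shared input checking and error signalling.
#
# All conditions carry a "gelstrain_error" base class plus a specific class so
# callers (and the CLI wrapper) can react programmatically:
#   gelstrain_domain_error      invalid numeric input to a computation
#   gelstrain_data_error        malformed file / table
#   gelstrain_config_error      malformed run configuration
#   gelstrain_no_crossover      sweep has G' != G'' throughout
#   gelstrain_multiple_crossovers  more than one G'/G'' sign change
#   gelstrain_degenerate_relaxation  non-decaying relaxation data
#   gelstrain_fit_error         optimizer failed to converge
#   gelstrain_geometry_error    contour geometry violated
#   gelstrain_non_star_shaped   a sector ray cuts the contour more than once
#   gelstrain_unachievable_frequency / _modulus   design target outside range
#   gelstrain_construction_error  spectrum construction root not bracketed

abort_gelstrain <- function(message, class, ...) {
  abort(message, class = c(class, "gelstrain_error"), ...)
}

abort_domain <- function(message, ...) {
  abort_gelstrain(message, "gelstrain_domain_error", ...)
}

abort_data <- function(message, ...) {
  abort_gelstrain(message, "gelstrain_data_error", ...)
}

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_domain(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (finite && !is.finite(x)) {
    abort_domain(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort_domain(sprintf("`%s` must be > 0, got %g.", name, x))
  }
  if (nonnegative && x < 0) {
    abort_domain(sprintf("`%s` must be >= 0, got %g.", name, x))
  }
  invisible(x)
}

check_numeric_vector <- function(x, name, positive = FALSE,
                                 nonnegative = FALSE, min_length = 1L) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_domain(sprintf("`%s` must be a finite numeric vector.", name))
  }
  if (length(x) < min_length) {
    abort_domain(sprintf("`%s` must have at least %d values.", name,
                         min_length))
  }
  if (positive && any(x <= 0)) {
    abort_domain(sprintf("all values of `%s` must be > 0.", name))
  }
  if (nonnegative && any(x < 0)) {
    abort_domain(sprintf("all values of `%s` must be >= 0.", name))
  }
  invisible(x)
}

check_strictly_increasing <- function(x, name) {
  if (any(diff(x) <= 0)) {
    abort_domain(sprintf("`%s` must be strictly increasing.", name))
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "input") {
  if (!is.data.frame(data)) {
    abort_data(sprintf("%s must be a data frame.", what))
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_data(sprintf("%s is missing required column(s): %s.", what,
                       paste0("`", missing, "`", collapse = ", ")),
               missing_columns = missing)
  }
  invisible(data)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  check_number(seed, "seed", nonnegative = TRUE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
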