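#' Random design of experiments over the modulus range
#'
#' Draws `n` modulus samples from `[E_low, E_high]` MPa. The default
#' budget (15 samples over 0.8-15 MPa) spans stiff to compliant tissue.
#' Sampling is uniform random under a mandatory seed; `method = "lhs"`
#' switches to a Latin-hypercube design when the `lhs` package is
#' available.
#'
#' @param n Number of samples (>= 3), default 15.
#' @param E_low,E_high Modulus range in MPa, default 0.8 and 15.
#' @param seed Integer seed; the design is reproducible given the seed.
#' @param method `"uniform"` (default) or `"lhs"`.
#' @return Tibble with columns `sample`, `E_mpa`.
#' @export
#' @examples
#' sample_design(seed = 1)
sample_design <- function(n = 15, E_low = 0.8, E_high = 15, seed,
                          method = c("uniform", "lhs")) {
  method <- match.arg(method)
  if (n < 3) abort("At least 3 design samples are required.")
  if (E_low >= E_high) abort("E_low must be below E_high.")
  if (missing(seed)) abort("A seed is required for a reproducible design.")
  E <- with_seed(seed, {
    if (method == "lhs") {
      if (!requireNamespace("lhs", quietly = TRUE)) {
        abort("method = 'lhs' needs the lhs package.")
      }
      E_low + (E_high - E_low) * as.numeric(lhs::randomLHS(n, 1))
    } else {
      runif(n, E_low, E_high)
    }
  })
  tibble::tibble(sample = seq_len(n), E_mpa = E)
}

#' Fit the quadratic response-surface surrogate
#'
#' Ordinary least squares of the forward-model responses on the basis
#' `(1, E, E^2)`: `f(E) = beta1 + beta2 E + beta3 E^2`. Exactly quadratic
#' responses are recovered to machine precision.
#'
#' @param E Modulus samples, MPa (>= 3 distinct values).
#' @param response Forward-model responses (strain in percent or orifice
#'   area in mm^2), same length as `E`.
#' @param response_label One of `"strain_annulus"`, `"strain_sinus"`,
#'   `"strain_STJ"`, `"orifice_area"` (or any descriptive string).
#' @return An object of class `quad_surrogate` with coefficients `beta`,
#'   the fitted `E_range`, `n_samples`, `residual_rms` and the design data.
#' @export
fit_surrogate <- function(E, response, response_label = "response") {
  if (length(E) != length(response)) {
    abort("`E` and `response` must have equal length.")
  }
  if (length(unique(E)) < 3) {
    abort("At least 3 distinct modulus values are required.")
  }
  if (any(!is.finite(response))) abort("Responses must be finite.")
  fit <- lm(response ~ E + I(E^2))
  beta <- unname(coef(fit))
  # a flat/collinear design (e.g. a saturated forward response) yields NA
  # higher-order coefficients; treat them as exactly zero
  beta[is.na(beta)] <- 0
  structure(list(
    beta = c(beta1 = beta[1], beta2 = beta[2], beta3 = beta[3]),
    E_range = range(E),
    n_samples = length(E),
    residual_rms = sqrt(mean(fit$residuals^2)),
    response_label = response_label,
    design = tibble::tibble(E_mpa = E, response = response)
  ), class = "quad_surrogate")
}

#' @export
predict.quad_surrogate <- function(object, E, ...) {
  b <- object$beta
  b[[1]] + b[[2]] * E + b[[3]] * E^2
}

#' @export
print.quad_surrogate <- function(x, ...) {
  cat(sprintf(
    "<quad_surrogate '%s': f(E) = %.4g %+.4g E %+.4g E^2, E in [%.2f, %.2f]>\n",
    x$response_label, x$beta[1], x$beta[2], x$beta[3],
    x$E_range[1], x$E_range[2]))
  invisible(x)
}

#' @describeIn fit_surrogate Coefficients as a tibble (term, estimate).
#' @param x A `quad_surrogate`.
#' @param ... Unused.
#' @export
tidy.quad_surrogate <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "E", "E^2"),
                 estimate = as.numeric(x$beta))
}

#' @describeIn fit_surrogate One-row fit summary.
#' @export
glance.quad_surrogate <- function(x, ...) {
  tibble::tibble(response_label = x$response_label,
                 n_samples = x$n_samples,
                 residual_rms = x$residual_rms,
                 E_low = x$E_range[1], E_high = x$E_range[2])
}

#' Solve the calibration cost function on a surrogate
#'
#' Finds the modulus at which the surrogate matches a measured observable:
#' the roots of `beta3 E^2 + beta2 E + (beta1 - measured) = 0` (linear
#' fallback when `|beta3| < 1e-12`). Real roots inside `E_range` are kept.
#' When two in-range roots exist, both reproduce the target; the root on
#' the physically meaningful branch where the response decreases with
#' stiffness (`f'(E) < 0`) is selected, ties broken toward the smaller
#' modulus, and `multiple_roots` is flagged for audit. With no real or
#' in-range root the argmin of the squared cost over the range (vertex or
#' boundary) is returned with `no_real_root` / `boundary_solution` flags.
#'
#' @param surrogate A `quad_surrogate`.
#' @param measured Measured observable in the surrogate's response units.
#' @param E_range Search range, MPa; defaults to the surrogate's fit range.
#' @return List with `E` (MPa, `NA` for a degenerate flat surrogate),
#'   `roots` (all real roots), `flags` (character vector).
#' @export
solve_cost <- function(surrogate, measured, E_range = surrogate$E_range) {
  b <- surrogate$beta
  lo <- E_range[1]; hi <- E_range[2]
  flags <- character(0)
  a2 <- b[[3]]; a1 <- b[[2]]; a0 <- b[[1]] - measured
  fprime <- function(E) a1 + 2 * a2 * E

  if (abs(a2) < 1e-12 && abs(a1) < 1e-12) {
    # flat surrogate: zero sensitivity to the modulus
    if (abs(a0) > 1e-9 * max(1, abs(measured))) {
      abort("Degenerate surrogate: response does not depend on E and does not match the measurement.")
    }
    return(list(E = NA_real_, roots = numeric(0), flags = "poor_fit"))
  }

  roots <- if (abs(a2) < 1e-12) {
    -a0 / a1
  } else {
    disc <- a1^2 - 4 * a2 * a0
    if (disc < 0) numeric(0) else {
      sq <- sqrt(disc)
      sort(c((-a1 - sq) / (2 * a2), (-a1 + sq) / (2 * a2)))
    }
  }
  in_range <- roots[roots >= lo & roots <= hi]

  if (length(in_range) >= 2) {
    flags <- c(flags, "multiple_roots")
    dec <- in_range[fprime(in_range) < 0]
    E <- if (length(dec)) min(dec) else min(in_range)
  } else if (length(in_range) == 1) {
    E <- in_range
  } else {
    # no usable root: minimize the squared cost over the range
    if (length(roots) == 0 && abs(a2) >= 1e-12) {
      flags <- c(flags, "no_real_root")
    }
    cand <- c(lo, hi)
    if (abs(a2) >= 1e-12) {
      vert <- -a1 / (2 * a2)
      if (vert > lo && vert < hi) cand <- c(cand, vert)
    }
    cost <- (predict(surrogate, cand) - measured)^2
    E <- cand[which.min(cost)]
    if (E %in% c(lo, hi)) flags <- c(flags, "boundary_solution")
  }
  list(E = unname(E), roots = unname(roots), flags = unique(flags))
}

# argmin over [lo, hi] of sum_r (f_r(E) - target_r)^2 for a list of
# surrogates; dense grid scan followed by local refinement with optimize()
minimize_combined <- function(surrogates, targets, E_range, grid_n = 2001) {
  obj <- function(E) {
    s <- 0
    for (i in seq_along(surrogates)) {
      s <- s + (predict(surrogates[[i]], E) - targets[[i]])^2
    }
    s
  }
  grid <- seq(E_range[1], E_range[2], length.out = grid_n)
  vals <- obj(grid)
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(grid_n, k + 1)]
  if (lo == hi) return(list(E = grid[k], objective = vals[k]))
  opt <- optimize(obj, c(lo, hi), tol = 1e-10)
  if (opt$objective <= vals[k]) {
    list(E = opt$minimum, objective = opt$objective)
  } else {
    list(E = grid[k], objective = vals[k])
  }
}
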