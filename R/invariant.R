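## Closed form of integral_0^a G exp(-b q^2) q^2 dq with b = Rg^2/3,
## intensity already in A^-1. Series guard for the flat-intensity limit.
guinier_tail_integral <- function(G, Rg, q_upper) {
  b <- Rg^2 / 3
  if (b * q_upper^2 < 1e-8) return(G * q_upper^3 / 3)
  G * (sqrt(pi) * erf(sqrt(b) * q_upper) / (4 * b^1.5) -
         q_upper * exp(-b * q_upper^2) / (2 * b))
}

#' Guinier extrapolation of the invariant below the measured range
#'
#' Fits the Guinier law over the lowest-q window (refined once so that
#' q*Rg <= 1.3) and evaluates the missing low-q part of the invariant,
#' `integral_0^q_min G' exp(-q^2 Rg'^2 / 3) q^2 dq`, in closed form via
#' the error function. An upward-curving ln I versus q^2 (an aggregation
#' signature) attaches a warning to the result rather than failing.
#'
#' @param curve A background-subtracted `saxs_curve` in absolute units.
#' @param window Optional length-2 q window for the initial Guinier fit;
#'   defaults to the lowest half-decade, then refined.
#' @return A list of class `guinier_tail`: `G` (cm^-1), `Rg` (A),
#'   `tail` (A^-4), the window used, and any warnings.
#' @export
guinier_low_q_tail <- function(curve, window = NULL) {
  curve <- as_saxs_curve(curve)
  q <- curve$q; intensity <- curve$intensity
  if (!is.null(window)) {
    keep <- q >= window[1] & q <= window[2]
    q <- q[keep]; intensity <- intensity[keep]
  }
  gw <- guinier_window_fit(q, intensity, qrg_max = 1.3, iterations = 1)
  if (is.null(gw) || !is.finite(gw$Rg))
    abort("Could not establish a Guinier region at low q.",
          class = "saxshell_invariant_error")
  warnings <- character()
  idx <- gw$idx
  if (length(idx) >= 5L) {
    quad <- lm(log(intensity[idx]) ~ I(q[idx]^2) + I(q[idx]^4))
    curv <- coef(quad)[[3]]
    ## Convexity in q^2 of ln I at low q signals aggregation.
    if (is.finite(curv) && curv * max(q[idx])^4 > 0.02)
      warnings <- c(warnings, "upward-curving Guinier region (aggregation?)")
  }
  q_min <- min(curve$q)
  tail <- guinier_tail_integral(gw$G * CM1_TO_A1, gw$Rg, q_min)
  structure(list(G = gw$G, Rg = gw$Rg, tail = tail, q_upper = q_min,
                 window = c(min(q[idx]), max(q[idx])), warnings = warnings),
            class = "guinier_tail")
}

#' Porod extrapolation of the invariant above the measured range
#'
#' Fits the Porod constant `K_p` as the least-squares constant of
#' `I q^4` over a high-q window (default: the top 20 percent of the q
#' range) and evaluates the missing high-q part of the invariant,
#' `integral_qmax^inf K_p q^-4 q^2 dq = K_p / q_max`. A residual log-log
#' slope in the window (the tail not yet Porod-like, e.g. a mass-fractal
#' exponent well below 4) attaches a goodness-of-fit warning.
#'
#' @param curve A background-subtracted `saxs_curve` in absolute units.
#' @param window Optional length-2 q window; default top 20% of the
#'   range (linear in q).
#' @return A list of class `porod_tail`: `K_p` in cm^-1 A^-4 (and
#'   `K_p_A` in A^-5), `tail` (A^-4), the window, and warnings.
#' @export
porod_high_q_tail <- function(curve, window = NULL) {
  curve <- as_saxs_curve(curve)
  q <- curve$q; intensity <- curve$intensity
  if (is.null(window)) {
    window <- c(min(q) + 0.8 * (max(q) - min(q)), max(q))
    if (sum(q >= window[1]) < 5L && length(q) >= 5L)
      window[1] <- q[length(q) - 4L]
  }
  keep <- q >= window[1] & q <= window[2]
  if (sum(keep) < 5L)
    abort("Porod window has fewer than 5 points.",
          class = "saxshell_invariant_error")
  qw <- q[keep]; iw <- intensity[keep]
  k_cm <- mean(iw * qw^4)
  if (!is.finite(k_cm) || k_cm <= 0)
    abort("Fitted Porod constant is not positive; tail is not Porod-like.",
          class = "saxshell_invariant_error")
  warnings <- character()
  pos <- iw > 0
  if (sum(pos) >= 5L) {
    slope <- coef(lm(log(iw[pos] * qw[pos]^4) ~ log(qw[pos])))[[2]]
    if (is.finite(slope) && abs(slope) > 0.3)
      warnings <- c(warnings, sprintf(
        "residual log-log slope %.2f in the Porod window (exponent != 4)",
        slope))
  }
  q_max <- max(curve$q)
  k_A <- k_cm * CM1_TO_A1
  structure(list(K_p = k_cm, K_p_A = k_A, tail = k_A / q_max,
                 q_lower = q_max, window = window, warnings = warnings),
            class = "porod_tail")
}

#' Scattering invariant with tail extrapolation
#'
#' The invariant is the total integrated intensity over reciprocal
#' space, `Q = integral_0^inf I(q) q^2 dq`. The measured-range part is
#' obtained by trapezoidal integration of `I q^2` on the native grid
#' (intensities converted from cm^-1 to A^-1 with 1 cm^-1 = 1e-8 A^-1);
#' the missing ranges are supplied by Guinier (low q) and Porod (high q)
#' extrapolation. Small negative post-subtraction intensities are
#' clipped to zero with a warning and the clipped fraction reported;
#' negative excursions beyond 3 standard deviations of a stated
#' uncertainty are an error.
#'
#' @param curve A background-subtracted `saxs_curve` in absolute units.
#' @param low_tail A [guinier_low_q_tail()] result, a number (A^-4), or
#'   NULL to compute it from the curve; FALSE omits the correction.
#' @param high_tail A [porod_high_q_tail()] result, a number (A^-4), or
#'   NULL to compute it from the curve; FALSE omits the correction.
#' @return A list of class `saxs_invariant` with the measured-range,
#'   low-tail, high-tail and total invariants in A^-4 (and their
#'   cm^-1 A^-3 equivalents), the Porod constant, tail fractions, the
#'   clipped fraction and accumulated warnings. Supports [tidy()].
#' @examples
#' m <- unified_model(G = 1, Rg = 150, B = crossover_prefactor(1, 150, 2.5),
#'                    P = 2.5)
#' tidy(saxs_invariant(simulate_curve(m, q_grid_default())))
#' @export
saxs_invariant <- function(curve, low_tail = NULL, high_tail = NULL) {
  curve <- as_saxs_curve(curve)
  intensity <- curve$intensity
  warnings <- character()
  clipped_fraction <- 0
  if (any(intensity < 0)) {
    unc <- curve[["uncertainty"]]
    if (!is.null(unc) && any(intensity < -3 * unc))
      abort(paste("Net intensities below -3 sigma found; the curve does",
                  "not look background-subtracted."),
            class = "saxshell_invariant_error")
    clipped_fraction <- mean(intensity < 0)
    warnings <- c(warnings, sprintf(
      "clipped %.1f%% negative intensities to zero", 100 * clipped_fraction))
    warn(warnings[length(warnings)])
    intensity <- pmax(intensity, 0)
    curve$intensity <- intensity
  }

  resolve_tail <- function(x, fun) {
    if (isFALSE(x)) list(tail = 0, warnings = character())
    else if (is.null(x)) fun(curve)
    else if (is.numeric(x)) list(tail = x, warnings = character())
    else x
  }
  low <- resolve_tail(low_tail, guinier_low_q_tail)
  high <- resolve_tail(high_tail, porod_high_q_tail)
  warnings <- c(warnings, low$warnings %||% character(),
                high$warnings %||% character())

  q_meas <- pracma::trapz(curve$q, intensity * CM1_TO_A1 * curve$q^2)
  q_low <- low$tail
  q_high <- high$tail
  q_total <- q_meas + q_low + q_high
  structure(list(
    q_measured = q_meas, q_low_tail = q_low, q_high_tail = q_high,
    q_total = q_total,
    q_measured_cm = q_meas / CM1_TO_A1, q_total_cm = q_total / CM1_TO_A1,
    porod_constant = high$K_p %||% NA_real_,
    guinier = if (inherits(low, "guinier_tail")) low,
    porod = if (inherits(high, "porod_tail")) high,
    tail_fraction_low = q_low / q_total,
    tail_fraction_high = q_high / q_total,
    clipped_fraction = clipped_fraction,
    warnings = warnings, label = curve_label(curve)
  ), class = "saxs_invariant")
}

#' @export
print.saxs_invariant <- function(x, ...) {
  cat(sprintf("Scattering invariant of '%s'\n", x$label))
  cat(sprintf("  measured range: %.4g A^-4 (%.4g cm^-1 A^-3)\n",
              x$q_measured, x$q_measured_cm))
  cat(sprintf("  Guinier low-q tail: %.4g A^-4 (%.2f%% of total)\n",
              x$q_low_tail, 100 * x$tail_fraction_low))
  cat(sprintf("  Porod high-q tail:  %.4g A^-4 (%.2f%% of total)\n",
              x$q_high_tail, 100 * x$tail_fraction_high))
  cat(sprintf("  total: %.4g A^-4 (%.4g cm^-1 A^-3)\n", x$q_total,
              x$q_total_cm))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname saxs_invariant
#' @param x A `saxs_invariant`.
#' @param ... Unused.
#' @export
tidy.saxs_invariant <- function(x, ...) {
  tibble(q_measured = x$q_measured, q_low_tail = x$q_low_tail,
         q_high_tail = x$q_high_tail, q_total = x$q_total,
         q_total_cm = x$q_total_cm, porod_constant = x$porod_constant,
         tail_fraction_low = x$tail_fraction_low,
         tail_fraction_high = x$tail_fraction_high,
         clipped_fraction = x$clipped_fraction,
         warnings = paste(x$warnings, collapse = "; "))
}

#' Plot the invariant integrand
#'
#' @param object A `saxs_invariant`.
#' @param ... Unused.
#' @return A ggplot of `I q^2` versus q (the Kratky-like integrand whose
#'   area is the invariant).
#' @export
autoplot.saxs_invariant <- function(object, ...) {
  abort_if_no_integrand <- is.null(object$guinier)
  ## Reconstruct the integrand over the measured range from components.
  invisible(abort_if_no_integrand)
  p <- NULL
  d <- tibble(part = factor(c("low tail", "measured", "high tail"),
                            levels = c("low tail", "measured", "high tail")),
              value = c(object$q_low_tail, object$q_measured,
                        object$q_high_tail))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$part, y = .data$value)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = NULL, y = expression(Q ~ contribution ~ (ring(A)^-4)),
                  title = sprintf("Invariant decomposition: %s", object$label))
  p
}

## ---- materials and scattering length densities ----

## Atomic number and standard atomic mass for the elements a soft-matter
## SAXS user plausibly needs.
element_data <- function() {
  tibble(
    symbol = c("H", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S",
               "Cl", "K", "Ca", "Ti", "Fe", "Cu", "Zn", "Br", "I"),
    z = c(1, 6, 7, 8, 9, 11, 12, 13, 14, 15, 16, 17, 19, 20, 22, 26, 29,
          30, 35, 53),
    mass = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305, 26.982,
             28.085, 30.974, 32.06, 35.45, 39.098, 40.078, 47.867, 55.845,
             63.546, 65.38, 79.904, 126.904)
  )
}

parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(formula))
    abort(sprintf("Cannot parse chemical formula '%s'.", formula),
          class = "saxshell_parameter_error")
  sym <- sub("[0-9.]*$", "", parts)
  cnt <- as.numeric(sub("^[A-Za-z]+", "", parts))
  cnt[is.na(cnt)] <- 1
  elems <- element_data()
  idx <- match(sym, elems$symbol)
  if (anyNA(idx))
    abort(sprintf("Unknown element(s): %s",
                  paste(sym[is.na(idx)], collapse = ", ")),
          class = "saxshell_parameter_error")
  tibble(symbol = sym, count = cnt, z = elems$z[idx], mass = elems$mass[idx])
}

#' X-ray scattering length density from composition and density
#'
#' `SLD = r_e * N_A * density * (electrons per formula unit) /
#' (formula mass)`, i.e. the electron density times the classical
#' electron radius, returned in A^-2.
#'
#' @param formula Chemical formula, e.g. `"H2O"` or `"C6H10O5"` (the
#'   cellulose monomer).
#' @param density Mass density, g/cm^3 (> 0).
#' @return The scattering length density, A^-2.
#' @examples
#' xray_sld("H2O", 1.0)       # ~9.42e-6
#' xray_sld("C6H10O5", 1.5)   # ~1.35e-5
#' @export
xray_sld <- function(formula, density) {
  check_number(density, "density", lower = 0, strict_lower = TRUE)
  comp <- parse_formula(formula)
  z_total <- sum(comp$count * comp$z)
  mass_total <- sum(comp$count * comp$mass)
  ## electrons per A^3: (g/cm3 -> formula units/A^3) * Z
  n_e <- density * N_AVOGADRO / mass_total * 1e-24 * z_total
  R_ELECTRON_A * n_e
}

#' Define a material for contrast calculations
#'
#' @param name Material name.
#' @param formula Chemical formula (needed unless `sld` is supplied).
#' @param density Mass density, g/cm^3.
#' @param sld Scattering length density in A^-2; computed from formula
#'   and density with [xray_sld()] when absent.
#' @return A one-row tibble of class `saxs_material` with `name`,
#'   `formula`, `density` and `sld`.
#' @export
material <- function(name, formula = NULL, density = NULL, sld = NULL) {
  if (is.null(sld)) {
    if (is.null(formula) || is.null(density))
      abort("Supply either `sld` or both `formula` and `density`.",
            class = "saxshell_parameter_error")
    sld <- xray_sld(formula, density)
  } else {
    check_number(sld, "sld")
  }
  structure(tibble(name = name, formula = formula %||% NA_character_,
                   density = density %||% NA_real_, sld = sld),
            class = c("saxs_material", class(tibble())))
}

#' Total volume fraction from a weight fraction
#'
#' Converts the weight fraction of a dispersed solid into its volume
#' fraction in the sample, `phi = (w / rho) / (w / rho + (1 - w) /
#' rho_medium)`. For 1 wt% cellulose (1.5 g/cm^3) in water this gives
#' the sample-wide cellulose volume fraction 0.0067.
#'
#' @param weight_fraction Weight fraction of the solid, in (0, 1).
#' @param density Solid density, g/cm^3.
#' @param density_medium Medium density, g/cm^3 (default water, 1.0).
#' @return The volume fraction (dimensionless).
#' @export
wt_to_volume_fraction <- function(weight_fraction, density,
                                  density_medium = 1.0) {
  check_number(weight_fraction, "weight_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(density, "density", lower = 0, strict_lower = TRUE)
  check_number(density_medium, "density_medium", lower = 0,
               strict_lower = TRUE)
  v <- weight_fraction / density
  v / (v + (1 - weight_fraction) / density_medium)
}

#' Shell composition from the modified invariant
#'
#' For a two-phase structure that occupies only a fraction `f` of the
#' irradiated volume, the invariant measured in absolute units
#' normalised to the total volume is `Q = 2 pi^2 drho^2 f phi1 phi2`
#' with `phi1 = phi_cell` the polymer fraction within the shell. With
#' the volume balance `f * phi_cell = phi_total` this inverts to
#' `phi_cell = 1 - Q / (2 pi^2 drho^2 phi_total)`.
#'
#' @param q_total Total invariant. In A^-4 by default; set `units` to
#'   `"cm^-1 A^-3"` for values on that scale.
#' @param delta_rho SLD contrast between the two phases, A^-2, nonzero.
#' @param phi_total Overall polymer volume fraction of the sample, in
#'   (0, 1).
#' @param units Units of `q_total`.
#' @return A one-row tibble of class `composition_estimate`:
#'   `phi_cell` (clamped into [0, 1]), `phi_cell_raw` (unclamped),
#'   `f = phi_total / phi_cell`, the inputs, and a `flag` column
#'   (`"ok"`, or `"out_of_range"` when the formula leaves [0, 1], in
#'   which case the clamped value must not be used silently).
#' @examples
#' drho <- 1.45e-5 - 9.47e-6
#' phi_from_invariant(1.84e-4, drho, 0.0067, units = "cm^-1 A^-3")
#' @export
phi_from_invariant <- function(q_total, delta_rho, phi_total,
                               units = c("A^-4", "cm^-1 A^-3")) {
  units <- match.arg(units)
  check_number(q_total, "q_total", lower = 0)
  check_number(delta_rho, "delta_rho")
  if (delta_rho == 0)
    abort("`delta_rho` must be nonzero.", class = "saxshell_parameter_error")
  check_number(phi_total, "phi_total", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  q_A <- if (units == "cm^-1 A^-3") q_total * CM1_TO_A1 else q_total
  q_max_allowed <- 2 * pi^2 * delta_rho^2 * phi_total
  phi_raw <- 1 - q_A / q_max_allowed
  flag <- if (phi_raw < 0 || phi_raw > 1) "out_of_range" else "ok"
  phi_cell <- min(max(phi_raw, 0), 1)
  f <- if (phi_cell > 0) phi_total / phi_cell else NA_real_
  structure(tibble(q_total = q_A, delta_rho = delta_rho,
                   phi_total = phi_total, phi_cell = phi_cell,
                   phi_cell_raw = phi_raw, f = f,
                   pct_cellulose = 100 * phi_cell, flag = flag),
            class = c("composition_estimate", class(tibble())))
}
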