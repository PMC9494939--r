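#' One structural level of the unified Guinier/power-law model
#'
#' A level is the pair of Guinier and power-law relations describing one
#' size scale: `G` (cm^-1) the Guinier prefactor, `Rg` (A) the radius of
#' gyration of the compact structural component, `B` (cm^-1 A^-P) the
#' power-law prefactor and `P` the power-law exponent characterising the
#' fractal aspect of the structure (P < 3 mass fractal, 3 < P < 4
#' surface fractal, P = 4 the Porod limit of a smooth interface).
#'
#' @param G Guinier prefactor, cm^-1 (>= 0).
#' @param Rg Radius of gyration, A (> 0).
#' @param B Power-law prefactor, cm^-1 A^-P (>= 0).
#' @param P Power-law exponent, in (1, 4).
#' @return An object of class `unified_level`.
#' @export
unified_level <- function(G, Rg, B, P) {
  check_number(G, "G", lower = 0)
  check_number(Rg, "Rg", lower = 0, strict_lower = TRUE)
  check_number(B, "B", lower = 0)
  check_number(P, "P", lower = 1, upper = 4, strict_lower = TRUE,
               strict_upper = TRUE)
  structure(list(G = G, Rg = Rg, B = B, P = P), class = "unified_level")
}

#' Unified scattering model
#'
#' One or more unified structural levels plus a flat additive
#' background. Levels are ordered from the smallest size scale (level 1)
#' upward. For the porous-shell analysis a single level suffices.
#'
#' @param G,Rg,B,P Parameters of a single level (ignored when `levels`
#'   is supplied); see [unified_level()].
#' @param background Flat additive intensity, cm^-1 (>= 0).
#' @param levels Optional list of [unified_level()] objects, smallest
#'   scale first.
#' @return An object of class `unified_model`.
#' @examples
#' m <- unified_model(G = 1, Rg = 150, B = 1e-5, P = 2.5)
#' unified_intensity(c(0.01, 0.1), m)
#' @export
unified_model <- function(G = NULL, Rg = NULL, B = NULL, P = NULL,
                          background = 0, levels = NULL) {
  if (is.null(levels)) {
    if (is.null(G) || is.null(Rg) || is.null(B) || is.null(P))
      abort("Supply either G, Rg, B, P or a list of levels.",
            class = "saxshell_parameter_error")
    levels <- list(unified_level(G, Rg, B, P))
  } else {
    if (!length(levels) || !all(vapply(levels, inherits, logical(1),
                                       "unified_level")))
      abort("`levels` must be a non-empty list of unified_level objects.",
            class = "saxshell_parameter_error")
  }
  check_number(background, "background", lower = 0)
  structure(list(levels = levels, background = background),
            class = "unified_model")
}

#' @export
print.unified_model <- function(x, ...) {
  cat(sprintf("Unified model: %d level(s), background %g cm^-1\n",
              length(x$levels), x$background))
  for (i in seq_along(x$levels)) {
    l <- x$levels[[i]]
    cat(sprintf("  level %d: G = %g cm^-1, Rg = %g A, B = %g, P = %g\n",
                i, l$G, l$Rg, l$B, l$P))
  }
  invisible(x)
}

#' Evaluate the unified Guinier/power-law intensity
#'
#' For a single level,
#' `I(q) = G exp(-q^2 Rg^2 / 3) + B [erf(q Rg / sqrt(6))]^(3P) q^(-P) +
#' background`. For multi-level models the levels are summed with each
#' level's power-law term damped by the Guinier factor of the
#' next-smaller level (level 1 undamped), the standard unified
#' convention.
#'
#' @param q Scattering vector(s), A^-1, positive.
#' @param model A [unified_model()].
#' @return Intensities in cm^-1 (finite and strictly positive whenever
#'   any prefactor or the background is positive).
#' @export
unified_intensity <- function(q, model) {
  if (!inherits(model, "unified_model"))
    abort("`model` must be a unified_model.",
          class = "saxshell_parameter_error")
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    abort("`q` must be positive and finite.",
          class = "saxshell_parameter_error")
  out <- rep(model$background, length(q))
  for (i in seq_along(model$levels)) {
    l <- model$levels[[i]]
    guinier <- l$G * exp(-q^2 * l$Rg^2 / 3)
    damp <- if (i > 1L) {
      rg_small <- model$levels[[i - 1L]]$Rg
      exp(-q^2 * rg_small^2 / 3)
    } else 1
    power <- l$B * erf(q * l$Rg / sqrt(6))^(3 * l$P) * q^(-l$P)
    out <- out + guinier + damp * power
  }
  out
}

#' Power-law prefactor placing the Guinier/power-law crossover at a
#' chosen q
#'
#' Returns the `B` for which the Guinier term and the (erf-damped)
#' power-law term of a unified level are equal at `q_cross`. Used by the
#' synthetic-data generator when only `G`, `Rg` and `P` are known, to
#' put the crossover mid-grid.
#'
#' @param G,Rg,P Unified level parameters.
#' @param q_cross Crossover position, A^-1. Defaults to the geometric
#'   midpoint of the instrument grid.
#' @return The prefactor B, cm^-1 A^-P.
#' @export
crossover_prefactor <- function(G, Rg, P, q_cross = NULL) {
  q_cross <- q_cross %||% sqrt(7.5e-3 * 0.264)
  check_number(q_cross, "q_cross", lower = 0, strict_lower = TRUE)
  check_number(G, "G", lower = 0)
  check_number(Rg, "Rg", lower = 0, strict_lower = TRUE)
  check_number(P, "P", lower = 1, upper = 4, strict_lower = TRUE,
               strict_upper = TRUE)
  G * exp(-q_cross^2 * Rg^2 / 3) * q_cross^P /
    erf(q_cross * Rg / sqrt(6))^(3 * P)
}

#' Mass-fractal power-law prefactor
#'
#' For a mass-fractal level the Guinier and power-law prefactors are
#' linked by `B = G * P / Rg^P * gamma(P / 2)`. This produces curves
#' with a realistic Guinier-to-power-law transition near `q ~ 1/Rg` and
#' is the physically motivated alternative to the crossover-placement
#' convention of [crossover_prefactor()].
#'
#' @inheritParams crossover_prefactor
#' @return The prefactor B, cm^-1 A^-P.
#' @export
fractal_prefactor <- function(G, Rg, P) {
  check_number(G, "G", lower = 0)
  check_number(Rg, "Rg", lower = 0, strict_lower = TRUE)
  check_number(P, "P", lower = 1, upper = 4, strict_lower = TRUE,
               strict_upper = TRUE)
  G * P / Rg^P * gamma(P / 2)
}

#' Concentric layered-sphere density profile
#'
#' A spherical core plus concentric shells in a solvent: a 2-layer
#' profile is the simple core-shell sphere, a 3-layer profile the
#' spherical core with two shells used as the gross droplet model.
#'
#' @param radii Outer radius of each layer from the core outward, A,
#'   strictly increasing and positive.
#' @param layer_slds Scattering length density of each layer, A^-2 (one
#'   per layer).
#' @param solvent_sld Solvent scattering length density, A^-2.
#' @param number_density Particles per unit volume, A^-3.
#' @return An object of class `layered_sphere`.
#' @export
layered_sphere <- function(radii, layer_slds, solvent_sld, number_density) {
  if (!is.numeric(radii) || !length(radii) || any(!is.finite(radii)) ||
      any(radii <= 0) || (length(radii) > 1 && any(diff(radii) <= 0)))
    abort("`radii` must be positive, finite and strictly increasing.",
          class = "saxshell_parameter_error")
  if (!is.numeric(layer_slds) || length(layer_slds) != length(radii) ||
      any(!is.finite(layer_slds)))
    abort("`layer_slds` must supply one finite SLD per layer.",
          class = "saxshell_parameter_error")
  check_number(solvent_sld, "solvent_sld")
  check_number(number_density, "number_density", lower = 0)
  structure(list(radii = as.numeric(radii),
                 layer_slds = as.numeric(layer_slds),
                 solvent_sld = solvent_sld,
                 number_density = number_density),
            class = "layered_sphere")
}

## 3 (sin x - x cos x) / x^3 with a series guard near x = 0.
sphere_amplitude_factor <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

layered_sphere_amplitude <- function(q, profile) {
  n <- length(profile$radii)
  outer_sld <- c(profile$layer_slds[-1], profile$solvent_sld)
  A <- numeric(length(q))
  for (j in seq_len(n)) {
    drho <- profile$layer_slds[j] - outer_sld[j]
    if (drho == 0) next
    R <- profile$radii[j]
    V <- 4 / 3 * pi * R^3
    A <- A + drho * V * sphere_amplitude_factor(q * R)
  }
  A
}

#' Scattering intensity of a layered sphere
#'
#' `I(q) = number_density * A(q)^2` with the amplitude
#' `A(q) = sum_j (rho_j - rho_out,j) V_j 3[sin(qR_j) - qR_j cos(qR_j)] /
#' (qR_j)^3`, where `rho_out,j` is the SLD immediately outside layer j.
#' The forward limit is `I(0) = number_density (sum_j drho_j V_j)^2`.
#' Intensities are returned in cm^-1 (1 cm^-1 = 1e-8 A^-1).
#'
#' @param q Scattering vector(s), A^-1.
#' @param profile A [layered_sphere()] profile.
#' @return Non-negative intensities, cm^-1.
#' @export
layered_sphere_intensity <- function(q, profile) {
  if (!inherits(profile, "layered_sphere"))
    abort("`profile` must be a layered_sphere.",
          class = "saxshell_parameter_error")
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0))
    abort("`q` must be non-negative and finite.",
          class = "saxshell_parameter_error")
  outer_sld <- c(profile$layer_slds[-1], profile$solvent_sld)
  if (all(profile$layer_slds - outer_sld == 0))
    warn("All layers have zero contrast; the intensity is identically zero.")
  A <- layered_sphere_amplitude(q, profile)
  profile$number_density * A^2 / CM1_TO_A1
}

#' Assemble Stuhrmann decomposition terms
#'
#' The scattering of a dilute suspension of particles with an
#' inhomogeneous interior splits into a homogeneous (shape) term, a
#' heterogeneous (inner inhomogeneity) term and a cross term coupling
#' the two; for inhomogeneities much smaller than the particle the
#' cross term is negligible and is absent by default.
#'
#' @param shape Curve of the homogeneous particle shape (a `saxs_curve`
#'   or data frame with q/intensity), cm^-1.
#' @param hetero Curve of the inner inhomogeneities on the same grid.
#' @param cross Optional cross-term curve on the same grid.
#' @return A tibble of class `stuhrmann_terms` with columns `q`,
#'   `shape`, `hetero`, optionally `cross`, and `total`.
#' @export
stuhrmann_terms <- function(shape, hetero, cross = NULL) {
  shape <- as_saxs_curve(shape)
  hetero <- as_saxs_curve(hetero)
  same_grid <- function(a, b)
    length(a$q) == length(b$q) && all(a$q == b$q)
  if (!same_grid(shape, hetero))
    abort("Stuhrmann terms must share one q grid.",
          class = "saxshell_grid_error")
  out <- tibble(q = shape$q, shape = shape$intensity,
                hetero = hetero$intensity)
  if (!is.null(cross)) {
    cross <- as_saxs_curve(cross)
    if (!same_grid(shape, cross))
      abort("Stuhrmann terms must share one q grid.",
            class = "saxshell_grid_error")
    out$cross <- cross$intensity
  }
  out$total <- out$shape + out$hetero + (out[["cross"]] %||% 0)
  structure(out, class = c("stuhrmann_terms", class(tibble())))
}

#' Total intensity of a Stuhrmann decomposition
#'
#' Pointwise sum of the shape and heterogeneity terms (plus the cross
#' term when present).
#'
#' @param terms A [stuhrmann_terms()] tibble.
#' @return A `saxs_curve` of the total intensity.
#' @export
stuhrmann_total <- function(terms) {
  if (!inherits(terms, "stuhrmann_terms"))
    abort("`terms` must come from stuhrmann_terms().",
          class = "saxshell_parameter_error")
  saxs_curve(terms$q, terms$total, label = "stuhrmann total")
}

#' Is the droplet shape term negligible in the measured q range?
#'
#' Evaluates the size-polydispersity-smeared intensity of a layered
#' sphere over the grid and compares its maximum with a noise floor.
#' Smearing (a lognormal distribution of a common size scale factor with
#' mean 1) ensures the verdict reflects the decay of the form-factor
#' envelope rather than accidental form-factor nulls. Micron-scale
#' droplets, being much larger than the inverse of the smallest
#' measurable q, push their shape scattering to lower q than the
#' instrument observes; this check quantifies how completely.
#'
#' @param profile A [layered_sphere()] profile.
#' @param q Instrument q grid, A^-1.
#' @param noise_floor Positive intensity threshold, cm^-1. Either a
#'   scalar or one value per grid point.
#' @param polydispersity Relative width (sigma/mu) of the lognormal size
#'   distribution; 0 disables smearing.
#' @param n_quad Number of quadrature sizes used for the smearing.
#' @return A list of class `negligibility_report`: maximum smeared
#'   intensity, the q at which it occurs, the ratio to the noise floor,
#'   the verdict (`"negligible"` iff the maximum is below the floor
#'   everywhere), and `q_clear`, the smallest q beyond which the shape
#'   term stays below the floor (NA if it never does).
#' @export
shape_term_negligibility <- function(profile, q = q_grid_default(),
                                     noise_floor, polydispersity = 0.2,
                                     n_quad = 61) {
  if (!inherits(profile, "layered_sphere"))
    abort("`profile` must be a layered_sphere.",
          class = "saxshell_parameter_error")
  check_qgrid(q)
  if (!(is.numeric(noise_floor) && length(noise_floor) %in% c(1L, length(q)) &&
        all(noise_floor > 0)))
    abort("`noise_floor` must be positive (scalar or one value per q).",
          class = "saxshell_parameter_error")
  check_number(polydispersity, "polydispersity", lower = 0)
  if (max(profile$radii) < 1 / min(q))
    warn(paste("Largest radius is smaller than 1/q_min; the negligibility",
               "argument does not apply to such small particles."))
  if (polydispersity > 0) {
    sdlog <- sqrt(log(1 + polydispersity^2))
    scales <- qlnorm(ppoints(n_quad), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    curves <- vapply(scales, function(s) {
      p <- profile
      p$radii <- profile$radii * s
      layered_sphere_intensity(q, p)
    }, numeric(length(q)))
    smeared <- rowMeans(curves)
  } else {
    smeared <- layered_sphere_intensity(q, profile)
  }
  floor_vec <- rep_len(noise_floor, length(q))
  below <- smeared < floor_vec
  i_max_excess <- which.max(smeared / floor_vec)
  q_clear <- if (all(below)) min(q)
  else if (below[length(q)]) q[max(which(!below)) + 1L]
  else NA_real_
  structure(list(
    max_intensity = max(smeared),
    q_at_max = q[which.max(smeared)],
    noise_floor = noise_floor,
    ratio = smeared[i_max_excess] / floor_vec[i_max_excess],
    verdict = if (all(below)) "negligible" else "not negligible",
    q_clear = q_clear,
    smeared = saxs_curve(q, smeared, label = "smeared shape term"),
    polydispersity = polydispersity
  ), class = "negligibility_report")
}

#' @export
print.negligibility_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Shape-term negligibility: %s\n",
    "  max smeared intensity %.4g cm^-1 at q = %.4g A^-1\n",
    "  max intensity / noise floor = %.4g\n"),
    x$verdict, x$max_intensity, x$q_at_max, x$ratio))
  if (!is.na(x$q_clear))
    cat(sprintf("  below the floor for q >= %.4g A^-1\n", x$q_clear))
  invisible(x)
}

#' @rdname shape_term_negligibility
#' @param x A `negligibility_report`.
#' @param ... Unused.
#' @export
tidy.negligibility_report <- function(x, ...) {
  tibble(max_intensity = x$max_intensity, q_at_max = x$q_at_max,
         ratio = x$ratio, verdict = x$verdict, q_clear = x$q_clear,
         polydispersity = x$polydispersity)
}
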