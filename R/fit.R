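#' Configuration for the unified-model fit
#'
#' @param weighting Residual scheme: `"log"` (log-intensity residuals,
#'   the default — robust across the two-decade intensity range when no
#'   uncertainties are supplied), `"uncertainty"` (residuals divided by
#'   the per-point uncertainty) or `"unweighted"` (raw intensity
#'   residuals).
#' @param rg_bounds Lower/upper bounds on Rg, A.
#' @param p_bounds Open bounds on the power-law exponent.
#' @param max_iterations Maximum Levenberg-Marquardt iterations per
#'   start.
#' @param multi_start Number of starts: the automatic initial guess plus
#'   `multi_start - 1` jittered copies.
#' @param seed Seed for the start-point jitter (fits are deterministic
#'   for a fixed seed).
#' @param float_background Whether the flat background floats (default)
#'   or is fixed at zero.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(weighting = c("log", "uncertainty", "unweighted"),
                       rg_bounds = c(10, 2000), p_bounds = c(1 + 1e-6, 4 - 1e-6),
                       max_iterations = 200, multi_start = 5, seed = 1,
                       float_background = TRUE) {
  weighting <- match.arg(weighting)
  stopifnot(length(rg_bounds) == 2, rg_bounds[1] > 0, diff(rg_bounds) > 0,
            length(p_bounds) == 2, p_bounds[1] > 1, p_bounds[2] < 4)
  check_number(max_iterations, "max_iterations", lower = 1)
  check_number(multi_start, "multi_start", lower = 1)
  check_number(seed, "seed")
  structure(list(weighting = weighting, rg_bounds = rg_bounds,
                 p_bounds = p_bounds, max_iterations = max_iterations,
                 multi_start = multi_start, seed = seed,
                 float_background = isTRUE(float_background)),
            class = "fit_config")
}

## Iterated Guinier fit (ln I vs q^2) over the lowest-q window with
## q * Rg <= qrg_max. Returns G, Rg, the window end and a validity flag.
guinier_window_fit <- function(q, intensity, qrg_max = 1.3, iterations = 2,
                               min_points = 5) {
  ok <- intensity > 0
  q <- q[ok]; intensity <- intensity[ok]
  if (length(q) < min_points) return(NULL)
  idx <- which(q <= min(q) * 10^0.5)
  if (length(idx) < min_points) idx <- seq_len(min(min_points, length(q)))
  rg <- NA_real_; g <- NA_real_
  for (it in seq_len(iterations + 1L)) {
    fit <- lm(log(intensity[idx]) ~ I(q[idx]^2))
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0)
      return(list(G = exp(coef(fit)[[1]]), Rg = NA_real_,
                  q_max = max(q[idx]), valid = FALSE, fit = fit,
                  idx = idx))
    rg <- sqrt(-3 * slope)
    g <- exp(coef(fit)[[1]])
    if (it > iterations) break
    idx <- which(q <= qrg_max / rg)
    if (length(idx) < min_points) idx <- seq_len(min(min_points, length(q)))
  }
  list(G = g, Rg = rg, q_max = max(q[idx]),
       valid = max(q[idx]) * rg <= 1.5, fit = fit, idx = idx)
}

#' Automatic starting values for the unified fit
#'
#' Derives a level-1 starting model from the data alone: the power-law
#' exponent from the median local log-log slope over the upper half of
#' the q range (clipped into the exponent bounds), Rg and G from an
#' iterated Guinier fit over the lowest-q window with q*Rg <= 1.3, B
#' from the high-q tail given the exponent, and the background from the
#' minimum tail intensity. When no Guinier knee lies in range, Rg is
#' pegged to its upper bound and flagged.
#'
#' @param curve A `saxs_curve` (>= 20 points spanning at least a decade
#'   in q).
#' @param config A [fit_config()] supplying the parameter bounds.
#' @return A [unified_model()] carrying a `flags` attribute (character
#'   vector; `"rg_at_upper_bound"` marks a missing Guinier knee).
#' @export
initial_guess <- function(curve, config = fit_config()) {
  curve <- as_saxs_curve(curve)
  q <- curve$q; intensity <- curve$intensity
  if (length(q) < 20L || max(q) / min(q) < 10)
    abort("Need at least 20 points spanning a decade in q.",
          class = "saxshell_parameter_error")
  if (all(intensity <= 0))
    abort("All intensities are non-positive; cannot form a guess.",
          class = "saxshell_parameter_error")
  flags <- character()

  ## Exponent: median central-difference log-log slope, upper half (log q).
  pos <- intensity > 0
  lq <- log(q[pos]); li <- log(intensity[pos])
  upper <- which(lq >= (min(lq) + max(lq)) / 2)
  upper <- upper[upper > 1 & upper < length(lq)]
  slopes <- (li[upper + 1L] - li[upper - 1L]) / (lq[upper + 1L] - lq[upper - 1L])
  p0 <- median(-slopes, na.rm = TRUE)
  p0 <- min(max(p0, config$p_bounds[1]), config$p_bounds[2])

  ## Rg and G from the iterated Guinier window.
  gw <- guinier_window_fit(q, intensity)
  if (is.null(gw) || !isTRUE(gw$valid) || !is.finite(gw$Rg) ||
      gw$Rg > config$rg_bounds[2]) {
    rg0 <- config$rg_bounds[2]
    g0 <- max(intensity)
    flags <- c(flags, "rg_at_upper_bound")
  } else {
    rg0 <- max(gw$Rg, config$rg_bounds[1])
    g0 <- gw$G
  }

  ## Background from the minimum tail intensity; B from the raw tail.
  bkg0 <- if (config$float_background) 0.5 * max(min(intensity), 0) else 0
  tail_idx <- which(lq >= (min(lq) + max(lq)) / 2)
  qt <- q[pos][tail_idx]; it <- intensity[pos][tail_idx]
  b0 <- median(it * qt^p0 / erf(qt * rg0 / sqrt(6))^(3 * p0))
  b0 <- max(b0, 0)

  model <- unified_model(G = g0, Rg = rg0, B = b0, P = p0, background = bkg0)
  attr(model, "flags") <- flags
  model
}

model_from_par <- function(par) {
  unified_model(G = par[["G"]], Rg = par[["Rg"]], B = par[["B"]],
                P = par[["P"]], background = par[["background"]])
}

fit_residual_fun <- function(q, intensity, uncertainty, weighting) {
  tiny <- .Machine$double.xmin
  switch(weighting,
    log = {
      keep <- intensity > 0
      function(par) {
        m <- unified_intensity(q[keep], model_from_par(par))
        log(pmax(m, tiny)) - log(intensity[keep])
      }
    },
    uncertainty = {
      if (is.null(uncertainty) || any(uncertainty <= 0))
        abort("Uncertainty weighting needs positive uncertainties.",
              class = "saxshell_parameter_error")
      function(par)
        (unified_intensity(q, model_from_par(par)) - intensity) / uncertainty
    },
    unweighted = function(par)
      unified_intensity(q, model_from_par(par)) - intensity
  )
}

#' Fit the level-1 unified model to a scattering curve
#'
#' Bounded Levenberg-Marquardt least squares started from
#' [initial_guess()] plus `multi_start - 1` jittered starts; the
#' converged start with the lowest chi-square wins (ties broken toward
#' the smallest Rg so reporting is deterministic). The fit is
#' deterministic for a fixed `config$seed`.
#'
#' @param curve A `saxs_curve` or data frame with `q`, `intensity` and
#'   optionally `uncertainty` columns.
#' @param config A [fit_config()].
#' @return An object of class `unified_fit` with the fitted
#'   [unified_model()], a per-parameter tibble (estimates and standard
#'   errors), the reduced chi-square, a convergence flag and the
#'   residual curve. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' true <- unified_model(G = 1, Rg = 150, B = crossover_prefactor(1, 150, 2.5),
#'                       P = 2.5)
#' curve <- simulate_curve(true, q_grid_default())
#' fit <- fit_unified(curve)
#' tidy(fit)
#' @export
fit_unified <- function(curve, config = fit_config()) {
  curve <- as_saxs_curve(curve)
  q <- curve$q; intensity <- curve$intensity
  start_model <- initial_guess(curve, config)
  flags <- attr(start_model, "flags") %||% character()
  l1 <- start_model$levels[[1]]
  start <- c(G = l1$G, Rg = l1$Rg, B = l1$B, P = l1$P,
             background = start_model$background)

  lower <- c(G = 0, Rg = config$rg_bounds[1], B = 0, P = config$p_bounds[1],
             background = 0)
  upper <- c(G = Inf, Rg = config$rg_bounds[2], B = Inf,
             P = config$p_bounds[2],
             background = if (config$float_background) Inf else 0)
  clip <- function(par) pmin(pmax(par, lower), pmin(upper, .Machine$double.xmax))

  starts <- list(clip(start))
  if (config$multi_start > 1) {
    jittered <- with_seed(config$seed, {
      lapply(seq_len(config$multi_start - 1L), function(k) {
        par <- start
        par[["G"]] <- par[["G"]] * exp(rnorm(1, 0, 0.3))
        par[["B"]] <- max(par[["B"]], 1e-300) * exp(rnorm(1, 0, 0.5))
        par[["Rg"]] <- par[["Rg"]] * exp(rnorm(1, 0, 0.25))
        par[["P"]] <- par[["P"]] + runif(1, -0.4, 0.4)
        clip(par)
      })
    })
    starts <- c(starts, jittered)
  }
  ## Deterministic ladder of Rg scales guards against the power-law-only
  ## local minimum when the automatic guess misses the Guinier knee.
  g_low <- median(head(intensity[intensity > 0], 3))
  ladder <- lapply(c(50, 150, 600), function(rg_l) {
    par <- start
    par[["Rg"]] <- rg_l
    par[["G"]] <- max(g_low, .Machine$double.xmin)
    clip(par)
  })
  starts <- c(starts, ladder)

  res_fun <- fit_residual_fun(q, intensity, curve[["uncertainty"]],
                              config$weighting)
  ctrl <- minpack.lm::nls.lm.control(maxiter = config$max_iterations,
                                     ftol = 1e-15, ptol = 1e-12)
  runs <- lapply(starts, function(st) {
    tryCatch({
      fit <- minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                                fn = res_fun, control = ctrl)
      list(fit = fit, chisq = fit$deviance,
           converged = fit$info %in% c(1L, 2L, 3L, 4L))
    }, error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs))
    abort("All fit starts failed.", class = "saxshell_fit_error")

  conv <- vapply(runs, `[[`, logical(1), "converged")
  pool <- if (any(conv)) runs[conv] else runs
  chisq <- vapply(pool, `[[`, numeric(1), "chisq")
  best_chisq <- min(chisq)
  near <- which(chisq <= best_chisq * (1 + 1e-9) + 1e-300)
  rgs <- vapply(pool[near], function(r) r$fit$par[["Rg"]], numeric(1))
  best <- pool[[near[which.min(rgs)]]]
  if (!any(conv)) flags <- c(flags, "not_converged")

  par <- best$fit$par
  n_res <- length(res_fun(par))
  dof <- max(n_res - length(par), 1L)
  std_err <- tryCatch({
    s <- summary(best$fit)
    setNames(s$coefficients[, "Std. Error"], rownames(s$coefficients))
  }, error = function(e) setNames(rep(NA_real_, length(par)), names(par)))

  fitted_model <- model_from_par(par)
  fitted_int <- unified_intensity(q, fitted_model)
  structure(list(
    model = fitted_model,
    parameters = tibble(term = names(par), estimate = unname(par),
                        std.error = unname(std_err[names(par)])),
    reduced_chisq = best$chisq / dof,
    converged = best$converged,
    flags = flags,
    weighting = config$weighting,
    n_starts = length(runs),
    iterations = best$fit$niter,
    residuals = tibble(q = q, observed = intensity, fitted = fitted_int,
                       residual = intensity - fitted_int),
    label = curve_label(curve),
    config = config
  ), class = "unified_fit")
}

#' @export
print.unified_fit <- function(x, ...) {
  cat(sprintf("Unified level-1 fit of '%s' (%s residuals)\n", x$label,
              x$weighting))
  p <- x$parameters
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-10s %12.6g  (se %.3g)\n", p$term[i], p$estimate[i],
                p$std.error[i]))
  cat(sprintf("  reduced chi-square %.4g; converged: %s\n",
              x$reduced_chisq, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the parameters of a unified fit
#'
#' @param x A `unified_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.unified_fit <- function(x, ...) x$parameters

#' One-row summary of a unified fit
#'
#' @param x A `unified_fit`.
#' @param ... Unused.
#' @return A tibble with the fitted Rg, P, G, B, background, the
#'   reduced chi-square, convergence flag and number of points.
#' @export
glance.unified_fit <- function(x, ...) {
  est <- setNames(x$parameters$estimate, x$parameters$term)
  tibble(rg = est[["Rg"]], p = est[["P"]], g = est[["G"]], b = est[["B"]],
         background = est[["background"]],
         reduced_chisq = x$reduced_chisq, converged = x$converged,
         n = nrow(x$residuals), n_starts = x$n_starts,
         flags = paste(x$flags, collapse = ","))
}

#' Plot a unified fit
#'
#' @param object A `unified_fit`.
#' @param ... Unused.
#' @return A ggplot: data and fitted curve on log-log axes.
#' @export
autoplot.unified_fit <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#C23B22") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = expression(I(q) ~ (cm^-1)),
                  title = sprintf("Unified fit: %s", object$label))
}

#' Local log-log slope of a curve
#'
#' Least-squares slope of log intensity versus log q over a q window,
#' returned with the positive sign convention (a pure power law
#' `I = B q^-P` gives P).
#'
#' @param curve A `saxs_curve`.
#' @param q_window Length-2 numeric: window limits in A^-1 (inclusive).
#' @return The exponent (dimensionless).
#' @export
local_loglog_slope <- function(curve, q_window) {
  curve <- as_saxs_curve(curve)
  if (!is.numeric(q_window) || length(q_window) != 2L || diff(q_window) <= 0)
    abort("`q_window` must be an increasing pair of q values.",
          class = "saxshell_parameter_error")
  keep <- curve$q >= q_window[1] & curve$q <= q_window[2] & curve$intensity > 0
  if (sum(keep) < 5L)
    abort("Window contains fewer than 5 usable points.",
          class = "saxshell_parameter_error")
  fit <- lm(log(curve$intensity[keep]) ~ log(curve$q[keep]))
  -coef(fit)[[2]]
}
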