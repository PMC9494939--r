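#' Construct a one-dimensional scattering curve
#'
#' A scattering curve is a tibble with columns `q` (A^-1, strictly
#' increasing and positive), `intensity` (absolute units, cm^-1) and,
#' optionally, `uncertainty` (cm^-1, one standard deviation). The label
#' and the processing history (every subtraction, scaling or clipping
#' applied) are carried as attributes.
#'
#' @param q Scattering-vector magnitudes, A^-1.
#' @param intensity Absolute intensities, cm^-1.
#' @param uncertainty Optional per-point standard deviations, cm^-1.
#' @param label Optional sample label.
#' @param history Character vector of processing steps already applied.
#' @return A tibble of class `saxs_curve`.
#' @examples
#' saxs_curve(q = c(0.01, 0.02), intensity = c(2, 1), label = "demo")
#' @export
saxs_curve <- function(q, intensity, uncertainty = NULL, label = NULL,
                       history = character()) {
  check_qgrid(q)
  if (!is.numeric(intensity) || length(intensity) != length(q) ||
      any(!is.finite(intensity)))
    abort("`intensity` must be finite and the same length as `q`.",
          class = "saxshell_parameter_error")
  if (!is.null(uncertainty)) {
    if (!is.numeric(uncertainty) || length(uncertainty) != length(q) ||
        any(!is.finite(uncertainty)) || any(uncertainty < 0))
      abort("`uncertainty` must be non-negative and the same length as `q`.",
            class = "saxshell_parameter_error")
  }
  out <- tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  if (!is.null(uncertainty)) out$uncertainty <- as.numeric(uncertainty)
  new_saxs_curve(out, label = label, history = history)
}

new_saxs_curve <- function(data, label = NULL, history = character()) {
  structure(data,
            class = c("saxs_curve", class(tibble())),
            label = label, history = history)
}

#' Coerce a data frame to a scattering curve
#'
#' Accepts any data frame with columns `q` and `intensity` (and optional
#' `uncertainty`), so curves can round-trip through dplyr verbs.
#'
#' @param x A data frame or `saxs_curve`.
#' @return A `saxs_curve` tibble.
#' @export
as_saxs_curve <- function(x) {
  if (inherits(x, "saxs_curve")) return(x)
  if (!is.data.frame(x) || !all(c("q", "intensity") %in% names(x)))
    abort("Expected a data frame with columns `q` and `intensity`.",
          class = "saxshell_parameter_error")
  saxs_curve(x$q, x$intensity, uncertainty = x[["uncertainty"]],
             label = attr(x, "label"), history = attr(x, "history") %||%
               character())
}

curve_label <- function(curve) attr(curve, "label") %||% "curve"

curve_history <- function(curve) attr(curve, "history") %||% character()

add_history <- function(curve, step) {
  attr(curve, "history") <- c(curve_history(curve), step)
  curve
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("# SAXS curve '%s': %d points, q in [%.4g, %.4g] A^-1\n",
              curve_label(x), nrow(x), min(x$q), max(x$q)))
  h <- curve_history(x)
  if (length(h)) cat("# history:", paste(h, collapse = "; "), "\n")
  NextMethod()
}

#' Log-log plot of one or more scattering curves
#'
#' @param object A `saxs_curve`.
#' @param ... Unused.
#' @return A ggplot object (intensity vs q on log-log axes, with error
#'   bars when uncertainties are present).
#' @export
autoplot.saxs_curve <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7)
  if ("uncertainty" %in% names(object))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$intensity - .data$uncertainty,
                               .Machine$double.xmin),
                   ymax = .data$intensity + .data$uncertainty),
      linewidth = 0.3, alpha = 0.4)
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = expression(I(q) ~ (cm^-1)),
                  title = curve_label(object))
}

#' Read a reduced 1-D scattering curve from a plain-text file
#'
#' Reads whitespace-separated columns `q intensity [uncertainty]`.
#' Lines starting with `#` and non-numeric header lines are skipped,
#' rows containing non-finite values are dropped (counted in the
#' history), q given in nm^-1 is converted to A^-1, rows are sorted by
#' q, and exact duplicate q values are averaged with a warning.
#'
#' @param path Path to the file.
#' @param units Units of the q column on input.
#' @param label Sample label; defaults to the file name.
#' @return A `saxs_curve`.
#' @export
read_saxs <- function(path, units = c("1/angstrom", "1/nm"), label = NULL) {
  units <- match.arg(units)
  if (!file.exists(path))
    abort(sprintf("File not found: %s", path), class = "saxshell_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  ncol_use <- if (length(fields)) max(lengths(fields)) else 0L
  parse_row <- function(f) {
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2L || any(is.na(v[1:2]))) return(NULL)
    c(v[1], v[2], if (length(v) >= 3L) v[3] else NA_real_)
  }
  rows <- Filter(Negate(is.null), lapply(fields, parse_row))
  mat <- do.call(rbind, rows)
  n_raw <- length(lines)
  if (is.null(mat)) mat <- matrix(numeric(), ncol = 3)
  keep <- is.finite(mat[, 1]) & is.finite(mat[, 2]) & mat[, 1] > 0
  n_dropped <- n_raw - sum(keep)
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 10L)
    abort(sprintf("Fewer than 10 valid data rows in %s.", path),
          class = "saxshell_io_error")
  q <- mat[, 1]
  if (units == "1/nm") q <- q / 10
  ord <- order(q)
  q <- q[ord]
  intensity <- mat[ord, 2]
  unc <- mat[ord, 3]
  has_unc <- ncol_use >= 3L && all(is.finite(unc))
  if (anyDuplicated(q)) {
    warn("Duplicate q values found; averaging duplicates.")
    grp <- match(q, unique(q))
    intensity <- as.numeric(tapply(intensity, grp, mean))
    if (has_unc) unc <- as.numeric(tapply(unc, grp, mean))
    q <- unique(q)
  }
  hist <- c(sprintf("read %s (units %s)", basename(path), units),
            if (n_dropped > 0) sprintf("dropped %d invalid rows", n_dropped))
  saxs_curve(q, intensity, uncertainty = if (has_unc) unc,
             label = label %||% sub("\\.[^.]*$", "", basename(path)),
             history = hist)
}

#' Write a scattering curve to a plain-text file
#'
#' Writes whitespace-separated columns (q in A^-1, intensity and
#' optional uncertainty in cm^-1) preceded by `#` comment lines that
#' record the label and processing history, so a round trip through
#' [read_saxs()] preserves the values.
#'
#' @param curve A `saxs_curve` (or data frame with q/intensity columns).
#' @param path Output path.
#' @param comments Extra comment lines to embed (without the leading #).
#' @return `path`, invisibly.
#' @export
write_saxs <- function(curve, path, comments = character()) {
  curve <- as_saxs_curve(curve)
  hdr <- c(sprintf("label: %s", curve_label(curve)),
           "units: q 1/angstrom, intensity 1/cm",
           sprintf("history: %s", paste(curve_history(curve), collapse = "; ")),
           comments)
  cols <- c("q", "intensity", intersect("uncertainty", names(curve)))
  body <- do.call(paste, c(lapply(cols, function(cl)
    formatC(curve[[cl]], digits = 16, format = "g")), list(sep = "\t")))
  writeLines(c(paste("#", hdr), paste("#", paste(cols, collapse = "\t")), body),
             path)
  invisible(path)
}

#' Subtract a (scaled) background curve
#'
#' `I_out = I_sample - scale * I_background`. The background must be
#' measured on the identical grid, or cover the sample's q range, in
#' which case it is linearly interpolated onto the sample grid (recorded
#' in the history). Uncertainties are combined in quadrature when both
#' curves carry them.
#'
#' @param sample,background `saxs_curve` objects.
#' @param scale Dimensionless scale factor applied to the background
#'   (transmission correction folded in).
#' @return The background-subtracted `saxs_curve`.
#' @export
subtract_background <- function(sample, background, scale = 1) {
  sample <- as_saxs_curve(sample)
  background <- as_saxs_curve(background)
  check_number(scale, "scale")
  interpolated <- FALSE
  if (length(background$q) == length(sample$q) &&
      all(background$q == sample$q)) {
    bg_i <- background$intensity
    bg_u <- background[["uncertainty"]]
  } else {
    if (min(background$q) > min(sample$q) || max(background$q) < max(sample$q))
      abort("Background grid does not cover the sample q range.",
            class = "saxshell_io_error")
    bg_i <- stats::approx(background$q, background$intensity,
                          xout = sample$q)$y
    bg_u <- if (!is.null(background[["uncertainty"]]))
      stats::approx(background$q, background$uncertainty, xout = sample$q)$y
    interpolated <- TRUE
  }
  unc <- NULL
  if (!is.null(sample[["uncertainty"]]) && !is.null(bg_u))
    unc <- sqrt(sample$uncertainty^2 + (scale * bg_u)^2)
  else if (!is.null(sample[["uncertainty"]]))
    unc <- sample$uncertainty
  out <- saxs_curve(sample$q, sample$intensity - scale * bg_i,
                    uncertainty = unc, label = curve_label(sample),
                    history = curve_history(sample))
  add_history(out, sprintf(
    "subtracted background '%s' (scale %g%s)", curve_label(background),
    scale, if (interpolated) ", interpolated" else ""))
}

#' Scale a curve to absolute units
#'
#' Multiplies intensities (and uncertainties) by a calibration factor
#' determined from a secondary standard such as pre-calibrated glassy
#' carbon, and marks the curve as absolutely calibrated.
#'
#' @param curve A `saxs_curve`.
#' @param reference_factor Positive dimensionless calibration factor.
#' @return The calibrated `saxs_curve`.
#' @export
absolute_calibration <- function(curve, reference_factor) {
  curve <- as_saxs_curve(curve)
  check_number(reference_factor, "reference_factor", lower = 0,
               strict_lower = TRUE)
  unc <- curve[["uncertainty"]]
  out <- saxs_curve(curve$q, curve$intensity * reference_factor,
                    uncertainty = if (!is.null(unc)) unc * reference_factor,
                    label = curve_label(curve),
                    history = curve_history(curve))
  add_history(out, sprintf("absolute calibration (factor %g)",
                           reference_factor))
}
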