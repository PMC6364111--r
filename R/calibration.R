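#' Serial-dilution concentrations for a standard series
#'
#' Element-wise `stock x aliquot / final_volume`, preserving order -- the
#' usual volumetric-flask dilution scheme (aliquots of stock made up to a
#' common final volume).
#'
#' @param stock Stock concentration, ug/mL (non-negative).
#' @param aliquots Aliquot volumes, mL (positive, each <= `final`).
#' @param final Final adjusted volume, mL (positive).
#' @return Concentrations, ug/mL, same order as `aliquots`.
#' @examples
#' build_series(1191.8, c(0.1, 0.25, 0.5, 1, 2, 3), 5)
#' @export
build_series <- function(stock, aliquots, final) {
  if (stock < 0) stop("stock must be >= 0")
  if (final <= 0) stop("final must be > 0")
  if (any(aliquots <= 0)) stop("aliquots must be > 0")
  if (any(aliquots > final))
    stop("impossible dilution: aliquot exceeds final volume")
  stock * aliquots / final
}

#' Assemble a standard series for calibration
#'
#' @param analyte_name Analyte name.
#' @param stock_concentration Stock concentration, ug/mL.
#' @param aliquot_volumes Aliquot volumes, mL.
#' @param final_volume Final volume, mL.
#' @param areas Measured peak areas (response x seconds), one per level.
#' @return An object of class `standard_series` with derived
#'   `concentrations`.
#' @export
standard_series <- function(analyte_name, stock_concentration,
                            aliquot_volumes, final_volume, areas) {
  conc <- build_series(stock_concentration, aliquot_volumes, final_volume)
  if (length(areas) != length(conc))
    stop("areas must have one value per dilution level")
  structure(list(analyte_name = analyte_name,
                 stock_concentration = stock_concentration,
                 aliquot_volumes = aliquot_volumes,
                 final_volume = final_volume,
                 concentrations = conc, areas = as.numeric(areas)),
            class = "standard_series")
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on concentration, `Y = aX + b`, with
#' `r` the Pearson correlation between area and concentration and the
#' linear range set to the span of the series. At least three distinct
#' concentration levels are required.
#'
#' @param series A [standard_series()].
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `r`, `linear_range`, and (initially `NA`) `lod`, `loq`.
#' @export
fit_calibration <- function(series) {
  stopifnot(inherits(series, "standard_series"))
  x <- series$concentrations
  y <- series$areas
  if (length(unique(x)) < 3L)
    stop("need >= 3 distinct concentration levels to fit")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(list(analyte_name = series$analyte_name,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 r = stats::cor(x, y),
                 linear_range = range(x),
                 lod = NA_real_, loq = NA_real_),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration> %s: Y = %.4gX %+.4g, r = %.4f, range %.4g-%.4g ug/mL\n",
              x$analyte_name, x$slope, x$intercept, x$r,
              x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Detection and quantification limits from the S/N criterion
#'
#' LOD is the concentration whose peak height reaches three times the
#' baseline noise s.d.; LOQ the concentration reaching ten times. Hence
#' `lod = 3 noise_sd / height_per_conc`, `loq = 10 noise_sd /
#' height_per_conc`, and `loq / lod = 10 / 3` identically.
#'
#' @param noise_sd Baseline noise standard deviation, response units.
#' @param height_per_conc Peak height per unit concentration (response per
#'   ug/mL), typically measured on the lowest standard.
#' @return `list(lod =, loq =)`, ug/mL.
#' @export
estimate_lod_loq <- function(noise_sd, height_per_conc) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (height_per_conc <= 0) stop("height_per_conc must be > 0")
  list(lod = 3 * noise_sd / height_per_conc,
       loq = 10 * noise_sd / height_per_conc)
}

#' External-standard quantification from a calibration curve
#'
#' Inverts the calibration line: `X = (area - intercept) / slope`. Results
#' outside the fitted linear range are returned with attribute
#' `"out_of_range" = TRUE` and a warning, not rejected.
#'
#' @param curve A [fit_calibration()] result.
#' @param area Peak area (response x seconds).
#' @return Concentration, ug/mL.
#' @export
es_content <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero")
  x <- (area - curve$intercept) / curve$slope
  tol <- 1e-8 * diff(curve$linear_range)
  oor <- x < curve$linear_range[1] - tol | x > curve$linear_range[2] + tol
  if (any(oor)) {
    warning(sprintf("%s: %d prediction(s) outside linear range %.4g-%.4g",
                    curve$analyte_name, sum(oor),
                    curve$linear_range[1], curve$linear_range[2]))
    attr(x, "out_of_range") <- TRUE
  }
  x
}

#' Write a calibration report CSV
#'
#' One row per analyte: `analyte,slope,intercept,r,range_low,range_high,
#' lod,loq`.
#'
#' @param curves List of `calibration_curve` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(curves, path) {
  out <- do.call(rbind, lapply(curves, function(cv)
    data.frame(analyte = cv$analyte_name, slope = cv$slope,
               intercept = cv$intercept, r = cv$r,
               range_low = cv$linear_range[1],
               range_high = cv$linear_range[2],
               lod = cv$lod, loq = cv$loq)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
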