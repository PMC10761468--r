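#' Conductivity calibration curve
#'
#' Linear calibration mapping a conductivity reading (mS/cm) to a Tris
#' concentration (mM): conc = slope x kappa + intercept. The shipped
#' presets are the calibrations of the extract and raffinate sensors
#' (slopes 15.359 and 15.382 mM/(mS/cm), intercepts 0.3656 and 0.2993 mM).
#'
#' @param slope Slope in mM per mS/cm (> 0).
#' @param intercept Intercept in mM.
#' @return An object of class `cal_curve`.
#' @export
cal_curve <- function(slope, intercept) {
  if (slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  structure(list(slope = slope, intercept = intercept), class = "cal_curve")
}

#' @rdname cal_curve
#' @param stream `"extract"` or `"raffinate"`.
#' @export
cal_curve_preset <- function(stream = c("extract", "raffinate")) {
  switch(match.arg(stream),
         extract = cal_curve(15.359, 0.3656),
         raffinate = cal_curve(15.382, 0.2993))
}

#' Convert between conductivity and Tris concentration
#'
#' `conductivity_to_conc` applies the sensor calibration; `conc_to_conductivity`
#' is its exact inverse (no flooring, so the pair round-trips to machine
#' precision).
#'
#' @param kappa Conductivity reading(s) in mS/cm (>= 0).
#' @param cal A [cal_curve()].
#' @return Concentration in mM (or conductivity in mS/cm for the inverse).
#' @examples
#' conductivity_to_conc(1.0, cal_curve_preset("raffinate"))  # 15.68 mM
#' @export
conductivity_to_conc <- function(kappa, cal) {
  stopifnot(inherits(cal, "cal_curve"))
  if (any(kappa < 0)) stop("conductivity must be >= 0", call. = FALSE)
  cal$slope * kappa + cal$intercept
}

#' @rdname conductivity_to_conc
#' @param conc Concentration(s) in mM.
#' @export
conc_to_conductivity <- function(conc, cal) {
  stopifnot(inherits(cal, "cal_curve"))
  (conc - cal$intercept) / cal$slope
}

#' Synthetic conductivity sensor trace
#'
#' Renders the conductivity a calibrated sensor would report for a
#' simulated stream: the inverse calibration of the true concentration
#' plus Gaussian sensor noise, floored at zero (readings below the
#' calibration intercept saturate the floor, as on the real sensor).
#'
#' @param result An `smb_result`.
#' @param cal A [cal_curve()] for the stream's sensor.
#' @param stream `"extract"`, `"raffinate"` or `"waste"`.
#' @param species Channel carrying the salt (default `"tris"`).
#' @param noise_sd Gaussian noise standard deviation in mS/cm.
#' @param seed Optional integer seed.
#' @return A [chromatogram()] with channel `conductivity` (mS/cm).
#' @export
generate_conductivity_trace <- function(result, cal, stream = "raffinate",
                                        species = "tris", noise_sd = 0.01,
                                        seed = NULL) {
  stopifnot(inherits(result, "smb_result"), inherits(cal, "cal_curve"))
  trace <- result[[paste0(stream, "_trace")]]
  if (is.null(trace[[species]]))
    stop("no trace for species '", species, "' in stream '", stream, "'",
         call. = FALSE)
  kappa <- conc_to_conductivity(trace[[species]], cal)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    kappa <- kappa + rnorm(length(kappa), sd = noise_sd)
  }
  chromatogram(time_s = trace$time_s, conductivity = pmax(kappa, 0))
}
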