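#' Extracted-ion chromatogram
#'
#' Per scan, sums the intensity over the window `center_mz +- width`
#' (default +-0.02, the extraction width used for all molecules) and
#' returns the trace against scan time.
#'
#' @param series A `scan_series`.
#' @param center_mz Window center in m/z.
#' @param width Half-width of the window in m/z.
#' @return A [chromatogram()] with channel `xic` (cps).
#' @export
extract_xic <- function(series, center_mz, width = 0.02) {
  stopifnot(inherits(series, "scan_series"))
  j <- which(series$mz >= center_mz - width & series$mz <= center_mz + width)
  if (length(j) == 0) {
    warning("empty extraction window at m/z ", center_mz,
            "; returning zero trace")
    v <- numeric(length(series$scan_times))
  } else {
    v <- colSums(series$intensity[j, , drop = FALSE])
  }
  chromatogram(time_s = series$scan_times, xic = v)
}

#' Baseline chromatogram
#'
#' The summed intensity between m/z 400 and 500 per scan; used to
#' normalize signal traces against drifts of the spray and the
#' buffer-induced background.
#'
#' @param series A `scan_series`.
#' @param range m/z window (default `c(400, 500)`).
#' @return A [chromatogram()] with channel `baseline`.
#' @export
baseline_chromatogram <- function(series, range = c(400, 500)) {
  stopifnot(inherits(series, "scan_series"))
  j <- which(series$mz >= range[1] & series$mz <= range[2])
  if (length(j) == 0) {
    warning("empty baseline window; returning zero trace")
    v <- numeric(length(series$scan_times))
  } else {
    v <- colSums(series$intensity[j, , drop = FALSE])
  }
  chromatogram(time_s = series$scan_times, baseline = v)
}

#' Zero-charge protein reconstruction
#'
#' Transforms a multiply-charged m/z spectrum onto a neutral-mass grid: for
#' each candidate mass M the intensities at m/z = (M + z 1.00728)/z are
#' summed over all charge states whose m/z falls inside the input range
#' (default 1700-2600). The output grid runs from 5 to 20 kDa with a step
#' mass of 0.5 Da by default.
#'
#' @param spectrum An `ms_spectrum` covering the input range.
#' @param input_range m/z window used for the transform.
#' @param output_range Neutral-mass window in Da.
#' @param step Mass grid step in Da.
#' @return An object of class `recon_spectrum`: list with `mass`,
#'   `intensity`, `step`.
#' @export
reconstruct_protein <- function(spectrum, input_range = c(1700, 2600),
                                output_range = c(5000, 20000), step = 0.5) {
  stopifnot(inherits(spectrum, "ms_spectrum"))
  mass <- seq(output_range[1], output_range[2], by = step)
  intensity <- numeric(length(mass))
  z_max <- floor(output_range[2] / input_range[1])
  for (z in seq_len(z_max)) {
    mzz <- (mass + z * PROTON_MASS) / z
    ok <- mzz >= input_range[1] & mzz <= input_range[2]
    if (!any(ok)) next
    vals <- approx(spectrum$mz, spectrum$intensity, xout = mzz[ok],
                   rule = 1)$y
    vals[is.na(vals)] <- 0
    intensity[ok] <- intensity[ok] + vals
  }
  structure(list(mass = mass, intensity = intensity, step = step),
            class = "recon_spectrum")
}

#' Peak-group integral of a reconstruction
#'
#' Trapezoidal integral of the reconstruction over `center +- window`,
#' capturing the sodium-adduct satellites of a protein peak group. Using
#' the group integral rather than a single extracted ion makes the readout
#' robust against adduct redistribution at elevated buffer levels.
#'
#' @param recon A `recon_spectrum`.
#' @param center Group center in Da.
#' @param window Half-width in Da (> 0).
#' @return Integrated intensity (cps x Da).
#' @export
peak_group_integral <- function(recon, center, window) {
  stopifnot(inherits(recon, "recon_spectrum"))
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (center - window < recon$mass[1] ||
      center + window > recon$mass[length(recon$mass)])
    warning("integration window truncated to the reconstruction grid")
  j <- which(recon$mass >= center - window & recon$mass <= center + window)
  if (length(j) < 2) return(0)
  trapz(recon$mass[j], recon$intensity[j])
}

#' Apo-protein percentage per switching interval
#'
#' A_apo / (A_apo + A_holo) from the peak-group integrals of each
#' switching interval, aligned to the SMB switch boundaries. Intervals
#' where both integrals are zero are undefined and reported as `NA`.
#'
#' @param apo_integral,holo_integral Numeric vectors of per-interval
#'   peak-group integrals (>= 0).
#' @return Numeric vector of apo fractions in \[0, 1\] (`NA` where
#'   undefined).
#' @examples
#' apo_percentage(c(1, 0, 0), c(1, 2, 0))
#' @export
apo_percentage <- function(apo_integral, holo_integral) {
  stopifnot(length(apo_integral) == length(holo_integral))
  if (any(apo_integral < 0) || any(holo_integral < 0))
    stop("peak-group integrals must be >= 0", call. = FALSE)
  tot <- apo_integral + holo_integral
  out <- ifelse(tot > 0, apo_integral / tot, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " interval(s) with no detected protein reported as NA")
  out
}
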