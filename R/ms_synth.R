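#' m/z of a protonated species
#'
#' (M + n_Na (22.98977 - 1.00728) + z 1.00728) / z for charge z and n_Na
#' sodium adducts (each adduct replaces one proton on the neutral species).
#'
#' @param neutral_mass Neutral mass in Da.
#' @param z Charge state.
#' @param n_na Number of sodium adducts.
#' @return m/z value.
#' @examples
#' charge_mz(17566.0, 8)  # main holo-myoglobin peak
#' @export
charge_mz <- function(neutral_mass, z, n_na = 0) {
  (neutral_mass + n_na * SODIUM_ADDUCT_MASS + z * PROTON_MASS) / z
}

#' Default acquisition m/z grid
#'
#' Uniform grid, by default 0.01 spacing over the TOF acquisition range
#' m/z 400-2600, which resolves the +-0.02 extraction window with five
#' samples.
#'
#' @param from,to Range limits in m/z.
#' @param step Grid spacing.
#' @return Numeric vector of m/z values.
#' @export
default_mz_grid <- function(from = 400, to = 2600, step = 0.01) {
  seq(from, to, by = step)
}

#' Synthesize one native ESI-TOF spectrum
#'
#' Renders the expected spectrum of a composition (named concentrations;
#' proteins in g/L, buffer in mM) through the species response models:
#' Gaussian peaks for every charge state and sodium adduct, suppression of
#' suppressible species by the buffer concentration, a saturating buffer
#' ion peak, and buffer-dependent broadband baseline noise; optionally
#' Poisson counting noise on top.
#'
#' @param composition Named numeric vector of concentrations (names must
#'   match the model names; absent species are taken as 0).
#' @param models List of [ms_species_model()] (default
#'   [default_ms_models()]).
#' @param suppression A [suppression_model()].
#' @param mz m/z grid (default [default_mz_grid()]).
#' @param background Two numbers `c(floor, buffer_gain)`: expected baseline
#'   counts per grid point without buffer, and the additional counts at
#'   full buffer saturation.
#' @param noise If `TRUE`, Poisson counting noise is applied.
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `ms_spectrum`: list with `mz` and
#'   `intensity` (cps, >= 0).
#' @examples
#' sp <- synthesize_spectrum(c(holo = 0.01), mz = default_mz_grid(2100, 2300))
#' @export
synthesize_spectrum <- function(composition, models = default_ms_models(),
                                suppression = suppression_model(),
                                mz = default_mz_grid(),
                                background = c(2, 18), noise = TRUE,
                                seed = NULL) {
  if (any(composition < 0)) stop("concentrations must be >= 0", call. = FALSE)
  lambda <- expected_spectrum(composition, models, suppression, mz, background)
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    intensity <- as.numeric(rpois(length(lambda), lambda))
  } else intensity <- lambda
  structure(list(mz = mz, intensity = intensity), class = "ms_spectrum")
}

# Noise-free expected spectrum (Poisson mean) on the grid.
expected_spectrum <- function(composition, models, suppression, mz,
                              background = c(2, 18)) {
  c_tris <- if ("tris" %in% names(composition)) composition[["tris"]] else 0
  supp <- suppression_fraction(suppression, c_tris)
  step <- mz[2] - mz[1]
  lambda <- numeric(length(mz))
  for (m in models) {
    conc <- if (m$name %in% names(composition)) composition[[m$name]] else 0
    if (conc <= 0) next
    level <- if (m$saturating)
      m$response_factor * (1 - exp(-conc / m$saturation_conc))
    else m$response_factor * conc
    if (m$suppressible) level <- level * supp
    pt <- ms_peak_table(m)
    for (i in seq_len(nrow(pt))) {
      lo <- pt$mz[i] - 6 * m$peak_width
      hi <- pt$mz[i] + 6 * m$peak_width
      j <- max(1L, ceiling((lo - mz[1]) / step) + 1L):
           min(length(mz), floor((hi - mz[1]) / step) + 1L)
      if (j[1] > j[length(j)]) next
      lambda[j] <- lambda[j] + level * pt$share[i] *
        exp(-(mz[j] - pt$mz[i])^2 / (2 * m$peak_width^2))
    }
  }
  tris_model <- models[["tris"]]
  sat <- if (!is.null(tris_model))
    1 - exp(-c_tris / tris_model$saturation_conc)
  else 1 - exp(-c_tris / 0.5)
  lambda + background[1] + background[2] * sat
}

#' Synthesize a time series of native ESI scans
#'
#' TOF acquisition at fixed accumulation intervals (default 0.25 s): one
#' synthesized spectrum per scan, driven by a time-dependent composition.
#'
#' @param composition_fun Function of time (s) returning a named
#'   concentration vector, or a constant named vector.
#' @param scan_times Scan time stamps in s (uniformly spaced).
#' @param seed Integer seed; each scan uses an independent substream drawn
#'   from it.
#' @inheritParams synthesize_spectrum
#' @return An object of class `scan_series`: list with `mz`, `scan_times`,
#'   and an `intensity` matrix (length(mz) x length(scan_times)).
#' @export
synthesize_scan_series <- function(composition_fun, scan_times,
                                   models = default_ms_models(),
                                   suppression = suppression_model(),
                                   mz = default_mz_grid(),
                                   background = c(2, 18), noise = TRUE,
                                   seed = NULL) {
  if (is.numeric(composition_fun)) {
    const <- composition_fun
    composition_fun <- function(t) const
  }
  if (!is.null(seed)) set.seed(seed)
  intensity <- matrix(0, length(mz), length(scan_times))
  for (i in seq_along(scan_times)) {
    sp <- synthesize_spectrum(composition_fun(scan_times[i]), models,
                              suppression, mz, background, noise,
                              seed = NULL)
    intensity[, i] <- sp$intensity
  }
  structure(list(mz = mz, scan_times = scan_times, intensity = intensity),
            class = "scan_series")
}

#' Mean spectrum of a scan series (or a time slice of it)
#'
#' @param series A `scan_series`.
#' @param from,to Optional time window in s (inclusive).
#' @return An `ms_spectrum` averaging the selected scans.
#' @export
mean_spectrum <- function(series, from = -Inf, to = Inf) {
  stopifnot(inherits(series, "scan_series"))
  i <- which(series$scan_times >= from & series$scan_times <= to)
  if (length(i) == 0) stop("no scans in the requested window", call. = FALSE)
  structure(list(mz = series$mz,
                 intensity = rowMeans(series$intensity[, i, drop = FALSE])),
            class = "ms_spectrum")
}
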