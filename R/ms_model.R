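# ESI conventions: proton mass added per charge, sodium adduct replaces a
# proton on the neutral species (+Na - H).
PROTON_MASS <- 1.00728
SODIUM_ADDUCT_MASS <- 22.98977 - 1.00728  # +21.98249 Da per adduct

#' MS response model for one species
#'
#' Describes how a species appears in a native ESI-TOF spectrum: either a
#' multiply-charged protein envelope (charge states with weights, a
#' geometrically decaying ladder of sodium adducts) or a set of fixed m/z
#' peaks (small molecules such as the heme group or the Tris buffer ion).
#'
#' `response_factor` is calibrated on the zero-charge reconstruction: it is
#' the group-integrated intensity (cps x Da summed over the whole charge
#' envelope, i.e. the quantity read off a reconstruction peak-group
#' integral) per concentration unit at zero suppression. For fixed-peak
#' species it is the peak height (cps) per concentration unit of the most
#' abundant peak.
#'
#' @param name Species label (must match the composition names used later).
#' @param neutral_mass Neutral monomer mass in Da (protein envelopes).
#' @param charge_states Integer vector of charge states.
#' @param charge_weights Relative abundance per charge state (normalized
#'   internally).
#' @param adduct_count_max Maximum number of sodium adducts.
#' @param adduct_decay Geometric decay ratio of successive adduct
#'   abundances.
#' @param response_factor Response factor (see Details).
#' @param peak_width Gaussian peak sigma in m/z units.
#' @param fixed_mz Optional numeric vector of fixed peak positions (small
#'   molecules); overrides the charge-envelope mechanism.
#' @param fixed_weights Relative heights of the fixed peaks.
#' @param saturating If `TRUE` the response follows limited growth
#'   `1 - exp(-c / saturation_conc)` instead of linearity (detector
#'   saturation, used for the Tris background ion).
#' @param saturation_conc Concentration scale of the saturating response.
#' @param suppressible If `TRUE` the species is attenuated by the
#'   buffer-suppression model (proteins, heme); the buffer ion itself is
#'   not.
#' @return An object of class `ms_species_model`.
#' @export
ms_species_model <- function(name, neutral_mass = NA_real_,
                             charge_states = integer(), charge_weights = NULL,
                             adduct_count_max = 3, adduct_decay = 0.35,
                             response_factor = 1, peak_width = 0.05,
                             fixed_mz = NULL, fixed_weights = NULL,
                             saturating = FALSE, saturation_conc = 0.5,
                             suppressible = TRUE) {
  if (length(charge_states) > 0) {
    if (any(charge_states < 1)) stop("charges must be >= 1", call. = FALSE)
    if (!is.finite(neutral_mass) || neutral_mass <= 0)
      stop("neutral_mass must be > 0 for a charge envelope", call. = FALSE)
    if (is.null(charge_weights)) charge_weights <- rep(1, length(charge_states))
    charge_weights <- charge_weights / sum(charge_weights)
  } else if (is.null(fixed_mz)) {
    stop("either charge_states or fixed_mz must be given", call. = FALSE)
  }
  if (!is.null(fixed_mz)) {
    if (is.null(fixed_weights)) fixed_weights <- rep(1, length(fixed_mz))
    fixed_weights <- fixed_weights / max(fixed_weights)
  }
  m <- structure(list(name = name, neutral_mass = neutral_mass,
                      charge_states = as.integer(charge_states),
                      charge_weights = charge_weights,
                      adduct_count_max = as.integer(adduct_count_max),
                      adduct_decay = adduct_decay,
                      response_factor = response_factor,
                      peak_width = peak_width,
                      fixed_mz = fixed_mz, fixed_weights = fixed_weights,
                      saturating = saturating,
                      saturation_conc = saturation_conc,
                      suppressible = suppressible),
                 class = "ms_species_model")
  m$peaks <- ms_peak_table(m)  # cached; rendering is per-scan
  m
}

#' Peak table of a species model
#'
#' Expands a species model into individual Gaussian peak centers and
#' amplitude shares. For charge envelopes the amplitude share of peak
#' (z, n_Na) is `w_z w_n / (z sigma sqrt(2 pi))` so that the group
#' integral of the zero-charge reconstruction equals `response_factor x
#' concentration` exactly (each m/z Gaussian maps to a mass-domain Gaussian
#' of width z sigma).
#'
#' @param model An [ms_species_model()].
#' @return Data frame with `mz`, `share` (amplitude per unit response),
#'   `z`, `n_na`.
#' @export
ms_peak_table <- function(model) {
  stopifnot(inherits(model, "ms_species_model"))
  if (!is.null(model$peaks)) return(model$peaks)
  if (!is.null(model$fixed_mz)) {
    return(data.frame(mz = model$fixed_mz, share = model$fixed_weights,
                      z = NA_integer_, n_na = NA_integer_))
  }
  n_na <- 0:model$adduct_count_max
  w_na <- model$adduct_decay^n_na
  w_na <- w_na / sum(w_na)
  out <- do.call(rbind, lapply(seq_along(model$charge_states), function(i) {
    z <- model$charge_states[i]
    mz <- (model$neutral_mass + n_na * SODIUM_ADDUCT_MASS +
             z * PROTON_MASS) / z
    amp <- model$charge_weights[i] * w_na /
      (z * model$peak_width * sqrt(2 * pi))
    data.frame(mz = mz, share = amp, z = z, n_na = n_na)
  }))
  rownames(out) <- NULL
  out
}

#' Ionization suppression by a non-volatile buffer
#'
#' The detected fraction of an analyte as a function of the buffer (Tris)
#' concentration. The law is log-logistic,
#' f(c) = 1 / (1 + (c / c50)^h), fitted through the anchor points; f(0) = 1
#' by construction and f is monotone non-increasing. Default anchors place
#' the detected fraction at 88% for 0.01 mM and 35% for 1 mM buffer,
#' consistent with detection below 90% at 0.01 mM and below 40% at 1 mM.
#'
#' @param anchors Two-column matrix or data frame (conc mM, fraction) with
#'   at least two rows; fractions in (0, 1).
#' @return An object of class `suppression_model` with fitted `c50`
#'   (mM) and Hill slope `h`.
#' @examples
#' m <- suppression_model()
#' suppression_fraction(m, c(0, 0.01, 1))
#' @export
suppression_model <- function(anchors = cbind(conc = c(0.01, 1),
                                              fraction = c(0.88, 0.35))) {
  a <- as.data.frame(anchors)
  names(a) <- c("conc", "fraction")
  if (nrow(a) < 2) stop("need at least two anchor points", call. = FALSE)
  if (any(a$conc <= 0) || any(a$fraction <= 0) || any(a$fraction >= 1))
    stop("anchors need conc > 0 and fraction in (0, 1)", call. = FALSE)
  # logit(1 - f) linear in log c: ln(1/f - 1) = h (ln c - ln c50)
  y <- log(1 / a$fraction - 1)
  x <- log(a$conc)
  fit <- stats::lm(y ~ x)
  h <- unname(stats::coef(fit)[2])
  if (h <= 0) stop("anchors imply non-decreasing suppression", call. = FALSE)
  c50 <- exp(-unname(stats::coef(fit)[1]) / h)
  structure(list(c50 = c50, h = h, anchors = a), class = "suppression_model")
}

#' @rdname suppression_model
#' @param model A `suppression_model`.
#' @param tris_conc Buffer concentration(s) in mM (>= 0).
#' @return Detected fraction(s) in (0, 1\].
#' @export
suppression_fraction <- function(model, tris_conc) {
  stopifnot(inherits(model, "suppression_model"))
  if (any(tris_conc < 0)) stop("tris_conc must be >= 0", call. = FALSE)
  1 / (1 + (tris_conc / model$c50)^model$h)
}

#' Default native ESI species models of the reference desalting system
#'
#' Myoglobin with its non-covalently bound heme: holo-myoglobin (17566.0
#' Da) at charge states 7-9, apo-myoglobin (16950.5 Da) at charge states
#' 8-9 (the five-peak pattern seen in native spectra), the dissociated
#' heme group at m/z 616.18 with its oxidized form at 633.16 (1:4 relative
#' height), and the Tris buffer ion at m/z 593.23 with a saturating
#' (limited-growth) response. The holo response is anchored at a 46.4 kcps
#' reconstruction group integral for 0.01 g/L at zero buffer; the heme
#' response factor exceeds apo's (higher ion yield of the small molecule).
#'
#' @param peak_width Gaussian sigma in m/z (default 0.05).
#' @return Named list of [ms_species_model()] objects
#'   (`holo`, `apo`, `heme`, `tris`).
#' @export
default_ms_models <- function(peak_width = 0.05) {
  list(
    holo = ms_species_model("holo", neutral_mass = 17566.0,
                            charge_states = c(7L, 8L, 9L),
                            charge_weights = c(0.30, 0.45, 0.25),
                            response_factor = 46.4e3 / 0.01,  # cps Da per g/L
                            peak_width = peak_width),
    apo = ms_species_model("apo", neutral_mass = 16950.5,
                           charge_states = c(8L, 9L),
                           charge_weights = c(0.55, 0.45),
                           response_factor = 46.4e3 / 0.01,
                           peak_width = peak_width),
    # per g/L of free heme; set so the heme peak tops the apo envelope at
    # equimolar dissociation (higher ion yield of the small molecule)
    heme = ms_species_model("heme", fixed_mz = c(616.18, 633.16),
                            fixed_weights = c(1, 0.25),
                            response_factor = 7e7,
                            peak_width = peak_width),
    tris = ms_species_model("tris", fixed_mz = 593.23, fixed_weights = 1,
                            response_factor = 4800, saturating = TRUE,
                            saturation_conc = 0.5, suppressible = FALSE)
  )
}
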