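#' In-silico experiment plan
#'
#' A feed schedule for a complete synthetic desalting experiment: ordered
#' sections, each with a Tris feed concentration, a protein feed
#' concentration, and a number of SMB cycles. Column states and the MS
#' acquisition clock carry over between sections (the detector keeps
#' acquiring while the feed reservoir is exchanged).
#'
#' @param tris_mM Numeric vector of Tris feed concentrations per section.
#' @param mb_gL Protein feed concentration(s), recycled to the number of
#'   sections.
#' @param cycles Cycles per section (>= 1), recycled likewise.
#' @param seed Run-level seed; detector substreams are derived from it.
#' @param conductivity_noise_sd Conductivity sensor noise in mS/cm.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(tris_mM, mb_gL = 0.2, cycles = 3, seed = 42,
                            conductivity_noise_sd = 0.01) {
  if (length(tris_mM) == 0) stop("empty plan: no sections", call. = FALSE)
  n <- length(tris_mM)
  sections <- data.frame(section = seq_len(n), tris_mM = tris_mM,
                         mb_gL = rep_len(mb_gL, n),
                         cycles = as.integer(rep_len(cycles, n)))
  if (any(sections$cycles < 1)) stop("cycles must be >= 1", call. = FALSE)
  if (any(sections$tris_mM < 0) || any(sections$mb_gL < 0))
    stop("feed concentrations must be >= 0", call. = FALSE)
  structure(list(sections = sections, seed = as.integer(seed),
                 conductivity_noise_sd = conductivity_noise_sd),
            class = "experiment_plan")
}

#' Preset experiment plans
#'
#' `"stepwise_tris"`: the Tris feed concentration is raised stepwise
#' through 0, 1, 5, 10, 50, 100 mM at constant 0.2 g/L protein; eleven
#' cycles for the initial buffer-only section, three cycles for each
#' subsequent concentration. `"constant_tris"`: a constant 10 mM Tris /
#' 0.2 g/L protein feed run for six cycles.
#'
#' @param name Preset name.
#' @param seed Run-level seed.
#' @return An [experiment_plan()].
#' @export
preset_plan <- function(name = c("stepwise_tris", "constant_tris"), seed = 42) {
  switch(match.arg(name),
         stepwise_tris = experiment_plan(c(0, 1, 5, 10, 50, 100), mb_gL = 0.2,
                                         cycles = c(11, 3, 3, 3, 3, 3),
                                         seed = seed),
         constant_tris = experiment_plan(10, mb_gL = 0.2, cycles = 6,
                                         seed = seed))
}

#' Generate a complete synthetic desalting experiment
#'
#' Chains [simulate_smb()] over the plan's sections (column states carried
#' over; the acquisition clock runs continuously across feed exchanges),
#' renders the detectors, and returns everything an analysis would see
#' plus the ground truth it should recover:
#' conductivity traces of extract and raffinate (calibrated sensors with
#' Gaussian noise), per-scan extracted-ion traces of the buffer ion, the
#' heme group, the holo-protein main peak and the baseline window, and a
#' per-switch table of reconstruction peak-group integrals and apo
#' percentages.
#'
#' The protein reaching the detector is split into holo and apo forms at a
#' fixed dissociation fraction, with free heme equimolar to apo.
#'
#' @param plan An [experiment_plan()].
#' @param cfg An [smb_config()] (default [smb_preset()]).
#' @param col A [column_params()] or list of four.
#' @param species List of [species_params()]; channels `"tris"` and `"mb"`
#'   are expected.
#' @param models,suppression MS response models; see
#'   [default_ms_models()] and [suppression_model()].
#' @param cal Named list of [cal_curve()]s for `extract` and `raffinate`.
#' @param apo_fraction Dissociated (apo) fraction of the protein at the
#'   detector.
#' @param ms If `FALSE`, skip the MS detector (conductivity only).
#' @param scan_interval MS accumulation interval in s (0.25 s on the
#'   instrument; coarser values cut run time proportionally).
#' @param mz_step m/z grid step.
#' @param sample_dt SMB outlet sampling interval in s.
#' @param group_window Half-width in Da of the reconstruction peak-group
#'   integrals.
#' @param keep_mean_spectra Keep the per-switch mean spectra in the bundle
#'   (memory proportional to switches).
#' @param ... Passed to [simulate_smb()].
#' @return An object of class `run_bundle`; see Details.
#' @export
generate_run <- function(plan, cfg = smb_preset(), col = column_params(),
                         species = default_species(),
                         models = default_ms_models(),
                         suppression = suppression_model(),
                         cal = list(extract = cal_curve_preset("extract"),
                                    raffinate = cal_curve_preset("raffinate")),
                         apo_fraction = 0.08, ms = TRUE,
                         scan_interval = 0.25, mz_step = 0.01,
                         sample_dt = 1, group_window = 100,
                         keep_mean_spectra = FALSE, ...) {
  stopifnot(inherits(plan, "experiment_plan"))
  secs <- plan$sections
  results <- vector("list", nrow(secs))
  prev <- NULL
  truth <- NULL
  for (i in seq_len(nrow(secs))) {
    feed <- c(tris = secs$tris_mM[i], mb = secs$mb_gL[i])
    results[[i]] <- simulate_smb(cfg, col, species, feed_conc = feed,
                                 n_cycles = secs$cycles[i],
                                 sample_dt = sample_dt, init = prev, ...)
    prev <- results[[i]]
    tr <- results[[i]]$raffinate_trace
    truth <- rbind(truth, data.frame(section = i, time_s = tr$time_s,
                                     tris_raffinate = tr$tris,
                                     mb_raffinate = tr$mb,
                                     tris_feed = feed[["tris"]],
                                     mb_feed = feed[["mb"]]))
  }
  combined <- combine_results(results)
  conduct <- list(
    extract = generate_conductivity_trace(combined, cal$extract, "extract",
                                          noise_sd = plan$conductivity_noise_sd,
                                          seed = plan$seed + 1L),
    raffinate = generate_conductivity_trace(combined, cal$raffinate,
                                            "raffinate",
                                            noise_sd = plan$conductivity_noise_sd,
                                            seed = plan$seed + 2L))

  bundle <- list(plan = plan, config = cfg, columns = combined$columns,
                 species = combined$species,
                 sections = results, combined = combined,
                 conductivity = conduct, ground_truth = truth, cal = cal,
                 models = models, suppression = suppression,
                 apo_fraction = apo_fraction, seed = plan$seed)
  if (ms) {
    bundle$ms <- render_ms_detector(combined, results, models, suppression,
                                    apo_fraction, scan_interval, mz_step,
                                    group_window, keep_mean_spectra,
                                    seed = plan$seed + 3L)
  }
  class(bundle) <- "run_bundle"
  bundle
}

#' Default tracked species of the desalting system
#'
#' Tris buffer (121.14 g/mol, fully permeating) and myoglobin (17566
#' g/mol, fully excluded on a desalting SEC resin).
#'
#' @param tris_mM,mb_gL Feed concentrations.
#' @return List of two [species_params()].
#' @export
default_species <- function(tris_mM = 100, mb_gL = 0.2) {
  list(species_params("tris", 121.14, pore_access = 1, feed_conc = tris_mM),
       species_params("mb", 17566, pore_access = 0, feed_conc = mb_gL,
                      conc_unit = "g/L"))
}

# Concatenate chained section results into one pseudo-result spanning the
# whole run (global traces only; per-switch profiles stay per section).
combine_results <- function(results) {
  one <- results[[length(results)]]
  glue <- function(field) {
    parts <- lapply(results, `[[`, field)
    df <- do.call(rbind, lapply(parts, as.data.frame))
    do.call(chromatogram, c(list(time_s = df$time_s),
                            as.list(df[setdiff(names(df), "time_s")])))
  }
  out <- one
  out$extract_trace <- glue("extract_trace")
  out$raffinate_trace <- glue("raffinate_trace")
  out$waste_trace <- glue("waste_trace")
  out$switch_boundaries <- unlist(lapply(results, `[[`, "switch_boundaries"))
  out$cycle_boundaries <- unlist(lapply(results, `[[`, "cycle_boundaries"))
  out$start_time <- results[[1]]$start_time
  out$start_switch <- results[[1]]$start_switch
  out
}

# Streaming MS detector: per switch, synthesize scans one at a time,
# accumulate XIC traces, the baseline, the switch mean spectrum and its
# reconstruction peak-group integrals. Memory stays O(one spectrum).
render_ms_detector <- function(combined, results, models, suppression,
                               apo_fraction, scan_interval, mz_step,
                               group_window, keep_mean_spectra, seed) {
  mz <- default_mz_grid(step = mz_step)
  tr <- combined$raffinate_trace
  f_tris <- approxfun(tr$time_s, tr$tris, rule = 2)
  f_mb <- approxfun(tr$time_s, tr$mb, rule = 2)
  heme_mass_ratio <- 616.5 / 16950.5
  comp_at <- function(t) {
    mb <- f_mb(t)
    c(tris = f_tris(t), holo = (1 - apo_fraction) * mb,
      apo = apo_fraction * mb, heme = apo_fraction * mb * heme_mass_ratio)
  }
  holo_mz <- charge_mz(models$holo$neutral_mass, 8L)
  xic_centers <- c(tris = 593.23, heme = 616.18, holo = holo_mz)
  xic_idx <- lapply(xic_centers, function(cm)
    which(mz >= cm - 0.02 & mz <= cm + 0.02))
  base_idx <- which(mz >= 400 & mz <= 500)

  t0 <- results[[1]]$start_time
  bounds <- c(t0, combined$switch_boundaries)
  n_sw <- length(bounds) - 1
  section_of <- rep(seq_along(results),
                    vapply(results, function(r) 4L * r$n_cycles, 1L))

  scan_times_all <- c()
  xic <- list(tris = c(), heme = c(), holo = c(), baseline = c())
  sw_tab <- data.frame(section = section_of, switch = seq_len(n_sw),
                       t_start = bounds[-length(bounds)], t_end = bounds[-1],
                       apo_integral = NA_real_, holo_integral = NA_real_,
                       apo_pct = NA_real_, mean_tris_true = NA_real_,
                       mean_mb_true = NA_real_)
  mean_spectra <- if (keep_mean_spectra) vector("list", n_sw) else NULL

  set.seed(seed)
  for (s in seq_len(n_sw)) {
    st <- seq(bounds[s], bounds[s + 1] - scan_interval / 2, by = scan_interval)
    acc <- numeric(length(mz))
    xs <- matrix(0, length(st), 4)
    for (i in seq_along(st)) {
      sp <- synthesize_spectrum(comp_at(st[i]), models, suppression, mz,
                                noise = TRUE, seed = NULL)
      acc <- acc + sp$intensity
      xs[i, 1] <- sum(sp$intensity[xic_idx$tris])
      xs[i, 2] <- sum(sp$intensity[xic_idx$heme])
      xs[i, 3] <- sum(sp$intensity[xic_idx$holo])
      xs[i, 4] <- sum(sp$intensity[base_idx])
    }
    scan_times_all <- c(scan_times_all, st)
    xic$tris <- c(xic$tris, xs[, 1])
    xic$heme <- c(xic$heme, xs[, 2])
    xic$holo <- c(xic$holo, xs[, 3])
    xic$baseline <- c(xic$baseline, xs[, 4])
    msp <- structure(list(mz = mz, intensity = acc / length(st)),
                     class = "ms_spectrum")
    if (keep_mean_spectra) mean_spectra[[s]] <- msp
    rec <- reconstruct_protein(msp)
    sw_tab$apo_integral[s] <-
      peak_group_integral(rec, models$apo$neutral_mass, group_window)
    sw_tab$holo_integral[s] <-
      peak_group_integral(rec, models$holo$neutral_mass, group_window)
    sw_tab$mean_tris_true[s] <- mean(f_tris(st))
    sw_tab$mean_mb_true[s] <- mean(f_mb(st))
  }
  sw_tab$apo_pct <- suppressWarnings(
    apo_percentage(sw_tab$apo_integral, sw_tab$holo_integral))
  traces <- chromatogram(time_s = scan_times_all, tris = xic$tris,
                         heme = xic$heme, holo = xic$holo,
                         baseline = xic$baseline)
  list(xic = traces, switch_table = sw_tab, mz_step = mz_step,
       scan_interval = scan_interval, mean_spectra = mean_spectra)
}
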