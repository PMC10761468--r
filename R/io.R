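#' Default configuration
#'
#' Nested list of every tunable parameter in bench units, suitable for
#' writing to YAML and overriding per key. The `processing` block freezes
#' the MS post-processing constants (extraction half-width +-0.02 m/z,
#' baseline window 400-500, reconstruction input 1700-2600 onto 5-20 kDa
#' at 0.5 Da, 120 s switching, 0.25 s accumulation).
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    fluid = list(density_kg_m3 = 998, viscosity_pa_s = 1.002e-3),
    column = list(length_mm = 50, inner_diameter_mm = 3,
                  particle_diameter_um = 80, interstitial_porosity = 0.38,
                  particle_porosity = 0.6, n_cells = 60, dead_time_s = 0),
    species = list(
      tris = list(molar_mass = 121.14, pore_access = 1, feed_conc = 100,
                  conc_unit = "mM"),
      mb = list(molar_mass = 17566, pore_access = 0, feed_conc = 0.2,
                conc_unit = "g/L")),
    smb = list(diluent_flow = 122, extract_flow = 44, feed_flow = 15,
               raffinate_flow = 30, waste_flow = 63, switching_time_s = 120),
    calibration = list(extract = list(slope = 15.359, intercept = 0.3656),
                       raffinate = list(slope = 15.382, intercept = 0.2993)),
    ms = list(peak_width_mz = 0.05, apo_fraction = 0.08,
              scan_interval_s = 0.25, mz_step = 0.01),
    processing = list(xic_halfwidth_mz = 0.02, baseline_range = c(400, 500),
                      recon_input_range = c(1700, 2600),
                      recon_output_range_da = c(5000, 20000),
                      recon_step_da = 0.5)
  )
}

#' Read / write a configuration file
#'
#' YAML configuration merged over [default_config()]; keys absent from the
#' defaults trigger a warning (misspellings are never dropped silently).
#'
#' @param path YAML file path.
#' @param config For writing, a configuration list.
#' @return `read_config` returns the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  warn_unknown(user, defaults, prefix = NULL)
  modifyList(defaults, user)
}

warn_unknown <- function(user, defaults, prefix) {
  if (!is.list(user) || !is.list(defaults)) return(invisible())
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0)
    warning("unknown configuration key(s): ",
            paste(c(prefix, extra[1]), collapse = "."),
            if (length(extra) > 1) paste0(" (+", length(extra) - 1, " more)"),
            call. = FALSE)
  for (k in intersect(names(user), names(defaults)))
    warn_unknown(user[[k]], defaults[[k]], c(prefix, k))
  invisible()
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build parameter objects from a configuration list
#'
#' @param config A configuration list as returned by [read_config()].
#' @return List with `fluid`, `column`, `species` (list), `smb`
#'   ([smb_config()]) and `cal` (calibration curves).
#' @export
config_objects <- function(config) {
  cc <- config$column
  col <- column_params(length = cc$length_mm,
                       inner_diameter = cc$inner_diameter_mm,
                       particle_diameter = cc$particle_diameter_um,
                       interstitial_porosity = cc$interstitial_porosity,
                       particle_porosity = cc$particle_porosity,
                       n_cells = cc$n_cells, dead_time = cc$dead_time_s)
  fl <- fluid_props(config$fluid$density_kg_m3, config$fluid$viscosity_pa_s)
  sp <- lapply(names(config$species), function(nm) {
    s <- config$species[[nm]]
    species_params(nm, s$molar_mass, s$pore_access, s$feed_conc,
                   conc_unit = s$conc_unit)
  })
  sm <- config$smb
  cfg <- smb_config(sm$diluent_flow, sm$extract_flow, sm$feed_flow,
                    sm$waste_flow, raffinate_flow = sm$raffinate_flow,
                    switching_time = sm$switching_time_s)
  cal <- lapply(config$calibration, function(x) cal_curve(x$slope, x$intercept))
  list(fluid = fl, column = col, species = sp, smb = cfg, cal = cal)
}

#' Write a scan series to mzML
#'
#' Profile-mode mzML via the proteowizard backend of \pkg{mzR}. The
#' inverse reader returns the same scan count and per-scan total ion
#' current.
#'
#' @param series A `scan_series`.
#' @param path Output file path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_scan_series_mzml <- function(series, path) {
  stopifnot(inherits(series, "scan_series"))
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML export requires the mzR package", call. = FALSE)
  n <- length(series$scan_times)
  peaks <- lapply(seq_len(n), function(i)
    cbind(mz = series$mz, intensity = series$intensity[, i]))
  tic <- vapply(peaks, function(p) sum(p[, 2]), 1.0)
  bp <- vapply(peaks, function(p) p[which.max(p[, 2]), 1], 1.0)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = length(series$mz), totIonCurrent = tic,
    retentionTime = series$scan_times, basePeakMZ = bp,
    basePeakIntensity = vapply(peaks, function(p) max(p[, 2]), 1.0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(series$mz), highMZ = max(series$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, centroided = FALSE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(series$mz),
    scanWindowUpperLimit = max(series$mz))
  mzR::writeMSData(peaks, path, header = hdr)
  invisible(path)
}

#' @rdname write_scan_series_mzml
#' @export
read_scan_series_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML import requires the mzR package", call. = FALSE)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  mz <- pk[[1]][, 1]
  intensity <- vapply(pk, function(p) p[, 2], numeric(length(mz)))
  structure(list(mz = mz, scan_times = hdr$retentionTime,
                 intensity = intensity), class = "scan_series")
}

#' Write a scan series to compact long-format CSV
#'
#' Columns `scan_time`, `mz`, `intensity`; intended for small windows, not
#' full acquisitions.
#'
#' @param series A `scan_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_series_csv <- function(series, path) {
  stopifnot(inherits(series, "scan_series"))
  df <- data.frame(
    scan_time = rep(series$scan_times, each = length(series$mz)),
    mz = rep(series$mz, length(series$scan_times)),
    intensity = as.vector(series$intensity))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run bundle to a directory
#'
#' Emits conductivity CSVs, the MS extracted-ion trace CSV, the per-switch
#' table, the ground-truth table, and a JSON manifest (configuration
#' snapshot, seed, package version, output files with MD5 checksums)
#' sufficient to re-run the generator identically.
#'
#' @param bundle A `run_bundle` from [generate_run()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_run_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "run_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    if (inherits(obj, "chromatogram")) write_chromatogram(obj, p)
    else write.csv(obj, p, row.names = FALSE)
    files <<- c(files, name)
  }
  wr(bundle$conductivity$extract, "conductivity_extract.csv")
  wr(bundle$conductivity$raffinate, "conductivity_raffinate.csv")
  wr(bundle$ground_truth, "ground_truth.csv")
  if (!is.null(bundle$ms)) {
    wr(bundle$ms$xic, "ms_xic.csv")
    wr(bundle$ms$switch_table, "ms_switch_table.csv")
  }
  manifest <- list(
    seed = bundle$seed,
    package_version = as.character(packageVersion("musmb")),
    config = unclass(bundle$config),
    plan = list(sections = bundle$plan$sections,
                conductivity_noise_sd = bundle$plan$conductivity_noise_sd),
    calibration = lapply(bundle$cal, unclass),
    apo_fraction = bundle$apo_fraction,
    files = lapply(files, function(f)
      list(name = f, md5 = unname(tools::md5sum(file.path(dir, f)))))
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(mp)
}
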