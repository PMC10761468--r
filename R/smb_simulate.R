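#' Per-column packing heterogeneity
#'
#' Real column trains are never perfectly identical; slight packing
#' differences make the raffinate peak pattern recur with a period of one
#' full cycle (every fourth switch with four columns). This helper applies
#' a seeded multiplicative perturbation to the interstitial and particle
#' porosities of each column.
#'
#' @param col A [column_params()] template.
#' @param n Number of columns.
#' @param sd Relative standard deviation of the perturbation (default 1%).
#' @param seed Integer seed.
#' @return List of `n` [column_params()] objects.
#' @export
perturb_columns <- function(col, n = 4, sd = 0.01, seed = 1) {
  stopifnot(inherits(col, "column_params"))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f1 <- 1 + rnorm(1, sd = sd)
    f2 <- 1 + rnorm(1, sd = sd)
    column_params(length = col$length, inner_diameter = col$inner_diameter,
                  particle_diameter = col$particle_diameter,
                  interstitial_porosity = min(col$interstitial_porosity * f1,
                                              0.99),
                  particle_porosity = min(col$particle_porosity * f2, 0.99),
                  n_cells = col$n_cells, dead_time = col$dead_time)
  })
}

#' Simulate the four-zone open-loop SMB
#'
#' Solves the four columns in series for each switching interval with the
#' open-loop node balances (fresh diluent into zone 1; extract drawn after
#' zone 1; feed mixed in before zone 3, c_in = (Q2 c_out,Z2 + Q_F c_F)/Q3;
#' raffinate drawn after zone 3; the zone 4 outlet goes to waste), then
#' advances the port assignment so that every column moves one zone
#' upstream (countercurrent to the liquid flow). Column states persist
#' across switches, so start-up transients and cyclic steady state emerge
#' naturally.
#'
#' @param cfg An [smb_config()].
#' @param col A [column_params()] object, or a list of four (e.g. from
#'   [perturb_columns()]) for a heterogeneous train.
#' @param species A [species_params()] or list thereof.
#' @param feed_conc Named feed concentrations; defaults to each species'
#'   `feed_conc` field.
#' @param n_cycles Number of full cycles (4 switches each) to simulate.
#' @param sample_dt Outlet sampling interval in s.
#' @param init Optional continuation state: a previous `smb_result` (its
#'   final column states, time and switch counter are carried over), or
#'   `NULL` for a freshly equilibrated train.
#' @param fluid,rtol,atol Passed to [simulate_column()].
#' @return An object of class `smb_result`: per-stream outlet arrays
#'   (`profiles[[stream]]` of dim n_time x n_species x n_switch), assembled
#'   chromatograms (`extract_trace`, `raffinate_trace`, `waste_trace`),
#'   switch and cycle boundaries, final column states, and bookkeeping
#'   needed to chain runs.
#' @export
simulate_smb <- function(cfg, col, species, feed_conc = NULL, n_cycles = 4,
                         sample_dt = 1, init = NULL, fluid = fluid_props(),
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(cfg, "smb_config"))
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  species <- as_species_list(species)
  nm <- vapply(species, function(s) s$name, "")
  cols <- if (inherits(col, "column_params")) rep(list(col), 4) else col
  stopifnot(length(cols) == 4)
  if (is.null(feed_conc))
    feed_conc <- setNames(vapply(species, function(s) s$feed_conc, 1.0), nm)
  feed_conc <- feed_conc[nm]
  if (any(feed_conc < 0)) stop("feed concentrations must be >= 0", call. = FALSE)

  q <- zone_flows(cfg)
  ts <- cfg$switching_time
  nsw <- 4L * n_cycles
  t_local <- seq(0, ts, by = sample_dt)
  nt <- length(t_local)

  if (is.null(init)) {
    states <- lapply(cols, function(cc) column_state(cc, species))
    t0 <- 0
    sw0 <- 0L
  } else {
    stopifnot(inherits(init, "smb_result"))
    states <- init$states
    t0 <- init$end_time
    sw0 <- init$end_switch
  }

  empty <- array(0, c(nt, length(species), nsw),
                 dimnames = list(NULL, nm, NULL))
  profiles <- list(extract = empty, raffinate = empty, waste = empty)

  for (s in seq_len(nsw)) {
    gsw <- sw0 + s - 1L  # global switch index, 0-based
    assign_col <- function(zone) ((zone - 1L + gsw) %% 4L) + 1L
    inlet_fun <- vector("list", 4)
    inlet_fun[[1]] <- setNames(lapply(nm, function(x) function(t) rep(0, length(t))), nm)
    out_local <- vector("list", 4)
    for (zone in 1:4) {
      ci <- assign_col(zone)
      res <- simulate_column(cols[[ci]], species, inlet_fun[[zone]],
                             flow_rate = q[[zone]], duration = ts,
                             initial = states[[ci]], sample_dt = sample_dt,
                             fluid = fluid, rtol = rtol, atol = atol)
      states[[ci]] <- res$state
      out_local[[zone]] <- res$chromatogram
      if (zone < 4) {
        nxt <- setNames(lapply(nm, function(x) {
          f <- approxfun(res$chromatogram$time_s, res$chromatogram[[x]],
                         rule = 2)
          if (zone == 2) {
            cf <- feed_conc[[x]]
            function(t) (q[["Q2"]] * f(t) + cfg$feed_flow * cf) / q[["Q3"]]
          } else f
        }), nm)
        inlet_fun[[zone + 1]] <- nxt
      }
    }
    for (k in seq_along(nm)) {
      profiles$extract[, k, s] <- out_local[[1]][[nm[k]]]
      profiles$raffinate[, k, s] <- out_local[[3]][[nm[k]]]
      profiles$waste[, k, s] <- out_local[[4]][[nm[k]]]
    }
  }

  # assembled global traces: per switch drop the t = 0 sample so the grid
  # stays strictly increasing across the port-switch discontinuity
  gtime <- as.vector(vapply(seq_len(nsw), function(s)
    t0 + (s - 1) * ts + t_local[-1], numeric(nt - 1)))
  assemble <- function(arr) {
    chans <- lapply(seq_along(nm), function(k)
      as.vector(arr[-1, k, , drop = FALSE]))
    names(chans) <- nm
    do.call(chromatogram, c(list(time_s = gtime), chans))
  }

  structure(list(
    extract_trace = assemble(profiles$extract),
    raffinate_trace = assemble(profiles$raffinate),
    waste_trace = assemble(profiles$waste),
    profiles = profiles,
    t_local = t_local,
    switch_boundaries = t0 + ts * seq_len(nsw),
    cycle_boundaries = t0 + 4 * ts * seq_len(n_cycles),
    states = states,
    species = species,
    feed_conc = feed_conc,
    config = cfg,
    columns = cols,
    sample_dt = sample_dt,
    start_time = t0,
    end_time = t0 + nsw * ts,
    start_switch = sw0,
    end_switch = sw0 + nsw,
    n_cycles = n_cycles), class = "smb_result")
}

#' Overall mass balance of an SMB run
#'
#' Mass fed (feed stream plus initial column holdup) versus mass withdrawn
#' (extract + raffinate + waste) plus final holdup, per species. The
#' relative defect should be well below 1%.
#'
#' @param result An `smb_result` started from an empty train.
#' @param init_holdup Optional named vector of initial held-up mass (for
#'   chained runs).
#' @return Data frame with per-species fed, out, holdup and relative
#'   defect.
#' @export
smb_mass_balance <- function(result, init_holdup = NULL) {
  species <- result$species
  nm <- vapply(species, function(s) s$name, "")
  cfg <- result$config
  ts <- cfg$switching_time
  tl <- result$t_local
  dur <- result$end_time - result$start_time
  fed <- result$feed_conc * cfg$feed_flow / 60 * dur
  if (!is.null(init_holdup)) fed <- fed + init_holdup[nm]
  flows <- c(extract = cfg$extract_flow, raffinate = cfg$raffinate_flow,
             waste = cfg$waste_flow)
  out <- setNames(numeric(length(nm)), nm)
  for (stream in names(flows)) {
    arr <- result$profiles[[stream]]
    for (k in seq_along(nm)) {
      a <- sum(vapply(seq_len(dim(arr)[3]),
                      function(s) trapz(tl, arr[, k, s]), 1.0))
      out[k] <- out[k] + flows[[stream]] / 60 * a
    }
  }
  hold <- Reduce(`+`, lapply(seq_along(result$states), function(i)
    column_holdup(result$states[[i]], result$columns[[i]], species)))
  data.frame(species = nm, fed = as.numeric(fed), out = as.numeric(out),
             holdup = as.numeric(hold[nm]),
             defect = as.numeric(abs(fed - out - hold[nm]) / pmax(fed, 1e-300)))
}

#' Detect the cyclic steady state
#'
#' Finds the smallest cycle k (>= 2) whose raffinate concentration profile
#' differs from that of cycle k-1 by less than `tol` in relative L2 norm.
#'
#' @param result An `smb_result` covering at least two full cycles.
#' @param tol Relative L2 threshold (default 1e-2).
#' @param stream Stream to test (default `"raffinate"`).
#' @return Cycle index at which CSS is reached, or `NA_integer_` if never.
#' @export
detect_css <- function(result, tol = 1e-2, stream = "raffinate") {
  stopifnot(inherits(result, "smb_result"))
  arr <- result$profiles[[stream]]
  nsw <- dim(arr)[3]
  ncyc <- nsw %/% 4L
  if (ncyc < 2) stop("insufficient data: need >= 2 completed cycles",
                     call. = FALSE)
  nsp <- dim(arr)[2]
  cyc_profile <- function(k, j) as.vector(arr[, j, (k - 1) * 4 + 1:4])
  for (k in 2:ncyc) {
    # per-species relative change, so unit scales do not weight the norm
    rel <- vapply(seq_len(nsp), function(j) {
      p1 <- cyc_profile(k - 1, j)
      p2 <- cyc_profile(k, j)
      denom <- sqrt(sum(p2^2))
      if (denom == 0) {
        if (sqrt(sum(p1^2)) == 0) 0 else Inf
      } else sqrt(sum((p2 - p1)^2)) / denom
    }, 1.0)
    if (max(rel) < tol) return(as.integer(k))
  }
  NA_integer_
}

#' Desalting level
#'
#' 1 - (mean raffinate salt concentration) / (feed salt concentration).
#' The mean should be taken over cyclic-steady-state cycles only, so the
#' result is independent of the start-up transient.
#'
#' @param mean_raffinate_conc Mean salt concentration in the raffinate.
#' @param feed_conc Salt concentration in the feed (> 0), same unit.
#' @return Desalting level as a fraction in \[0, 1\].
#' @examples
#' desalting_level(1.93, 100)  # 0.9807
#' @export
desalting_level <- function(mean_raffinate_conc, feed_conc) {
  if (feed_conc <= 0) stop("feed_conc must be > 0", call. = FALSE)
  if (mean_raffinate_conc < 0)
    stop("mean_raffinate_conc must be >= 0", call. = FALSE)
  if (mean_raffinate_conc > feed_conc) {
    warning("raffinate concentration exceeds feed; desalting level clamped to 0")
    return(0)
  }
  1 - mean_raffinate_conc / feed_conc
}

#' Process metrics of an SMB run at cyclic steady state
#'
#' Computes, over the CSS cycles only: the flow-weighted mean raffinate
#' concentration per species, the desalting level of the salt species, and
#' the protein recovery in the raffinate (raffinate mass flow over feed
#' mass flow).
#'
#' @param result An `smb_result`.
#' @param salt,protein Channel names of the buffer salt and the protein.
#' @param css_cycle CSS cycle index; default from [detect_css()].
#' @param tol CSS tolerance when `css_cycle` is `NULL`.
#' @return List with `css_cycle`, `mean_raffinate_conc` (named),
#'   `desalting_level`, `protein_recovery_raffinate`.
#' @export
process_metrics <- function(result, salt = "tris", protein = "mb",
                            css_cycle = NULL, tol = 1e-2) {
  stopifnot(inherits(result, "smb_result"))
  if (is.null(css_cycle)) css_cycle <- detect_css(result, tol = tol)
  if (is.na(css_cycle))
    stop("cyclic steady state not reached; cannot compute CSS metrics",
         call. = FALSE)
  arr <- result$profiles$raffinate
  nm <- dimnames(arr)[[2]]
  nsw <- dim(arr)[3]
  sw <- ((css_cycle - 1) * 4 + 1):nsw
  tl <- result$t_local
  span <- (tl[length(tl)] - tl[1]) * length(sw)
  mean_conc <- vapply(seq_along(nm), function(k)
    sum(vapply(sw, function(s) trapz(tl, arr[, k, s]), 1.0)) / span, 1.0)
  names(mean_conc) <- nm
  dl <- if (salt %in% nm && result$feed_conc[[salt]] > 0)
    desalting_level(mean_conc[[salt]], result$feed_conc[[salt]]) else NA_real_
  rec <- if (protein %in% nm && result$feed_conc[[protein]] > 0) {
    raff_mass <- result$config$raffinate_flow * mean_conc[[protein]] * span
    feed_mass <- result$config$feed_flow * result$feed_conc[[protein]] * span
    raff_mass / feed_mass
  } else NA_real_
  list(css_cycle = css_cycle, mean_raffinate_conc = mean_conc,
       desalting_level = dl, protein_recovery_raffinate = rec)
}
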