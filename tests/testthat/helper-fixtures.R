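# Shared fixtures. Expensive multi-cycle SMB runs are computed once per test
# session and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fix_species <- function(tris_feed = 100, mb_feed = 0.2) {
  list(species_params("tris", 121.14, pore_access = 1, feed_conc = tris_feed),
       species_params("mb", 17566, pore_access = 0, feed_conc = mb_feed,
                      conc_unit = "g/L"))
}

fix_column <- function(n_cells = 60, ...) column_params(n_cells = n_cells, ...)

# Homogeneous 6-cycle run at the reference operating point, 100 mM Tris feed.
fix_smb_run <- function() {
  if (is.null(.fixtures$smb_run))
    .fixtures$smb_run <- simulate_smb(smb_preset(), fix_column(),
                                      fix_species(), n_cycles = 6)
  .fixtures$smb_run
}

# Heterogeneous train (1% porosity perturbations), 5 cycles.
fix_hetero_run <- function() {
  if (is.null(.fixtures$hetero_run)) {
    cols <- perturb_columns(fix_column(), sd = 0.01, seed = 3)
    .fixtures$hetero_run <- simulate_smb(smb_preset(), cols, fix_species(),
                                         n_cycles = 5)
  }
  .fixtures$hetero_run
}

# Small complete synthetic experiment: 100 mM Tris feed, 6 cycles (enough
# to pass the CSS criterion), with MS at a coarsened 2 s scan interval.
fix_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    plan <- experiment_plan(100, mb_gL = 0.2, cycles = 6, seed = 42)
    .fixtures$bundle <- generate_run(plan, scan_interval = 2)
  }
  .fixtures$bundle
}

# Independent hand-written transport correlations (test oracle; kept free of
# package helpers on purpose).
oracle_reynolds <- function(u, dp_m, rho, eta) u * dp_m * rho / eta
oracle_polson <- function(mw) 2.74e-9 * mw^(-1 / 3)
oracle_chung_wen <- function(u, dp_m, eps, rho, eta) {
  re <- u * dp_m * rho / eta
  u * dp_m * eps / (0.2 + 0.011 * (eps * re)^0.48)
}
oracle_wilson_geankoplis <- function(dm, u, dp_m, eps) {
  rp <- dp_m / 2
  1.09 * dm / (2 * rp * eps) * (eps * u * dp_m / dm)^0.33
}

# Brute-force zero-charge reconstruction: nested loops over candidate mass
# and charge, with hand-written linear interpolation on the uniform grid.
oracle_reconstruct <- function(spectrum, input_range = c(1700, 2600),
                               output_range = c(5000, 20000), step = 0.5) {
  mass <- seq(output_range[1], output_range[2], by = step)
  out <- numeric(length(mass))
  proton <- 1.00728
  mz0 <- spectrum$mz[1]
  dmz <- spectrum$mz[2] - spectrum$mz[1]
  nmz <- length(spectrum$mz)
  for (i in seq_along(mass)) {
    for (z in 1:floor(output_range[2] / input_range[1])) {
      mzz <- (mass[i] + z * proton) / z
      if (mzz < input_range[1] || mzz > input_range[2]) next
      i0 <- floor((mzz - mz0) / dmz) + 1
      if (i0 < 1 || i0 >= nmz) next
      x0 <- spectrum$mz[i0]; x1 <- spectrum$mz[i0 + 1]
      y0 <- spectrum$intensity[i0]; y1 <- spectrum$intensity[i0 + 1]
      out[i] <- out[i] + y0 + (y1 - y0) * ((mzz - x0) / (x1 - x0))
    }
  }
  list(mass = mass, intensity = out)
}
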