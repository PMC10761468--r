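models <- default_ms_models()
supp <- suppression_model()

test_that("suppression law honors its anchors and monotonicity", {
  expect_equal(suppression_fraction(supp, 0), 1.0)
  expect_lt(suppression_fraction(supp, 0.01), 0.90)
  expect_lt(suppression_fraction(supp, 1), 0.40)
  cc <- 10^seq(-2, 2, length.out = 40)
  f <- suppression_fraction(supp, cc)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
})

test_that("native spectrum of the protein shows five peaks at charges 7-9", {
  sp <- synthesize_spectrum(c(holo = 0.01, apo = 0.0008),
                            models, supp, noise = FALSE)
  # main (adduct-free) peak positions of holo z=7..9 and apo z=8..9
  centers <- c(charge_mz(17566, 7), charge_mz(17566, 8), charge_mz(17566, 9),
               charge_mz(16950.5, 8), charge_mz(16950.5, 9))
  expect_true(all(centers > 1700 & centers < 2600))
  for (cm in centers) {
    j <- which(abs(sp$mz - cm) < 0.03)
    background <- 2  # configured noise floor
    expect_gt(max(sp$intensity[j]), 10 * background)
  }
})

test_that("sodium adduct spacing in m/z is the replacement mass over z", {
  pt <- ms_peak_table(models$holo)
  p8 <- pt[pt$z == 8, ]
  expect_equal(diff(p8$mz), rep((22.98977 - 1.00728) / 8, 3),
               tolerance = 1e-9)
  # neutral-mass spacing ~22 Da per adduct
  expect_equal(diff(p8$mz)[1] * 8, 21.98249, tolerance = 1e-6)
})

test_that("no suppression leaves the calibrated response intact", {
  sp0 <- synthesize_spectrum(c(holo = 0.01), models, supp,
                             background = c(0, 0), noise = FALSE)
  rec <- reconstruct_protein(sp0)
  h <- peak_group_integral(rec, 17566, 100)
  expect_equal(h, models$holo$response_factor * 0.01, tolerance = 0.05)
})

test_that("XIC sums the window and vanishes off-peak", {
  st <- seq(0, 5, 0.25)
  ser <- synthesize_scan_series(c(heme = 1e-4), st, models, supp,
                                mz = default_mz_grid(600, 650),
                                background = c(0, 0), noise = FALSE)
  x_on <- extract_xic(ser, 616.18)
  x_off <- extract_xic(ser, 640.0)
  expect_true(all(x_on$xic > 0))
  expect_true(all(x_off$xic == 0))
  expect_warning(extract_xic(ser, 1000), "empty extraction window")
  # window of +-0.02 on a sigma = 0.05 Gaussian captures the summed samples
  peak_sum <- sum(ser$intensity[abs(ser$mz - 616.18) <= 0.02, 1])
  expect_equal(x_on$xic[1], peak_sum)
})

test_that("baseline trace is flat for constant input and scales linearly", {
  st <- seq(0, 10, 0.5)
  ser <- synthesize_scan_series(c(tris = 5), st, models, supp,
                                mz = default_mz_grid(400, 600),
                                noise = FALSE)
  b <- baseline_chromatogram(ser)
  expect_lt(sd(b$baseline) / mean(b$baseline), 1e-12)
  ser10 <- ser
  ser10$intensity <- 10 * ser$intensity
  b10 <- baseline_chromatogram(ser10)
  expect_equal(b10$baseline, 10 * b$baseline, tolerance = 1e-12)
})

test_that("zero-charge reconstruction equals the brute-force oracle", {
  set.seed(21)
  grid <- default_mz_grid(1700, 2600)
  for (i in 1:3) {
    n_prot <- sample(1:3, 1)
    comp <- setNames(runif(n_prot, 0.002, 0.02),
                     c("holo", "apo", "extra")[seq_len(n_prot)])
    mods <- models
    if (n_prot == 3)
      mods$extra <- ms_species_model("extra", neutral_mass = 12000,
                                     charge_states = 5:6,
                                     response_factor = 1e6)
    sp <- synthesize_spectrum(comp, mods, supp, mz = grid,
                              background = c(0, 0), noise = TRUE,
                              seed = 100 + i)
    fast <- reconstruct_protein(sp, output_range = c(11000, 18000))
    slow <- oracle_reconstruct(sp, output_range = c(11000, 18000))
    expect_equal(fast$mass, slow$mass)
    expect_equal(fast$intensity, slow$intensity, tolerance = 1e-12)
  }
})

test_that("reconstruction locates the protein mass to one grid step", {
  sp <- synthesize_spectrum(c(holo = 0.01), models, supp, noise = TRUE,
                            seed = 4)
  rec <- reconstruct_protein(sp)
  expect_lte(abs(rec$mass[which.max(rec$intensity)] - 17566.0), 0.5)
  empty <- synthesize_spectrum(c(holo = 0), models, supp,
                               background = c(0, 0), noise = FALSE)
  expect_true(all(reconstruct_protein(empty)$intensity == 0))
})

test_that("holo and apo reconstruct 615.5 Da apart", {
  sp <- synthesize_spectrum(c(holo = 0.01, apo = 0.01), models, supp,
                            background = c(0, 0), noise = FALSE)
  rec <- reconstruct_protein(sp)
  halves <- split(seq_along(rec$mass), rec$mass < 17250)
  m_holo <- rec$mass[halves[["FALSE"]]][which.max(rec$intensity[halves[["FALSE"]]])]
  m_apo <- rec$mass[halves[["TRUE"]]][which.max(rec$intensity[halves[["TRUE"]]])]
  expect_equal(m_holo - m_apo, 615.5, tolerance = 0.001)
})

test_that("all MS transforms are linear in the spectrum scale", {
  sp <- synthesize_spectrum(c(holo = 0.01, tris = 1), models, supp,
                            noise = TRUE, seed = 8)
  sp2 <- sp
  sp2$intensity <- 3 * sp$intensity
  r1 <- reconstruct_protein(sp)
  r2 <- reconstruct_protein(sp2)
  expect_equal(r2$intensity, 3 * r1$intensity, tolerance = 1e-12)
  expect_equal(peak_group_integral(r2, 17566, 100),
               3 * peak_group_integral(r1, 17566, 100), tolerance = 1e-12)
})

test_that("group integrals recover the generator's apo:holo ratio within 5%", {
  sp <- synthesize_spectrum(c(holo = 0.01, apo = 0.0008), models, supp,
                            background = c(0, 0), noise = FALSE)
  rec <- reconstruct_protein(sp)
  a <- peak_group_integral(rec, 16950.5, 100)
  h <- peak_group_integral(rec, 17566.0, 100)
  expect_equal(a / h, 0.08, tolerance = 0.05)
  # additivity over windows sharing one boundary grid point
  lo <- peak_group_integral(rec, 17541, 75)
  hi <- peak_group_integral(rec, 17691, 75)
  expect_equal(lo + hi, peak_group_integral(rec, 17616, 150),
               tolerance = 1e-9)
  expect_error(peak_group_integral(rec, 17566, 0), "window")
  expect_warning(peak_group_integral(rec, 5100, 500), "truncated")
})

test_that("apo percentage handles edge cases and stays near truth", {
  expect_equal(apo_percentage(0, 10), 0)
  expect_equal(apo_percentage(3, 3), 0.5)
  expect_warning(p <- apo_percentage(c(1, 0), c(1, 0)), "NA")
  expect_true(is.na(p[2]))
  expect_error(apo_percentage(-1, 1), ">= 0")
})

test_that("apo percentage is noisier on sub-switch windows", {
  # same total acquisition, windows of one switch vs a quarter switch
  comp_fun <- function(t)
    c(holo = 0.092 * (1 + 0.5 * sin(2 * pi * t / 120)),
      apo = 0.008 * (1 + 0.5 * cos(2 * pi * t / 120)))
  st <- seq(0, 480 - 2, 2)
  ser <- synthesize_scan_series(comp_fun, st, models, supp,
                                mz = default_mz_grid(1700, 2600, 0.02),
                                background = c(0, 0), noise = TRUE, seed = 17)
  est <- function(win) {
    bins <- split(seq_along(st), floor(st / win))
    vapply(bins, function(j) {
      ms <- structure(list(mz = ser$mz,
                           intensity = rowMeans(ser$intensity[, j, drop = FALSE])),
                      class = "ms_spectrum")
      rec <- reconstruct_protein(ms)
      apo_percentage(peak_group_integral(rec, 16950.5, 100),
                     peak_group_integral(rec, 17566, 100))
    }, 1.0)
  }
  full <- est(120)
  quarter <- est(30)
  expect_gt(sd(quarter), 2 * sd(full))
  expect_lt(sd(full) / mean(full), 0.1)
})

test_that("high buffer levels drown the cyclic pattern of the normalized signal", {
  cyc <- function(mean_tris) function(t)
    c(tris = mean_tris * (1 + 0.8 * sin(2 * pi * t / 120)))
  st <- seq(0, 480 - 2, 2)
  # modulation depth of the normalized signal at the cycle frequency
  depth <- vapply(c(0.02, 2), function(m) {
    ser <- synthesize_scan_series(cyc(m), st, models, supp,
                                  mz = default_mz_grid(400, 600),
                                  noise = TRUE, seed = 23)
    x <- extract_xic(ser, 593.23)$xic / baseline_chromatogram(ser)$baseline
    f <- Mod(fft(x - mean(x)))
    k <- length(st) * 2 / 120 + 1  # cycle frequency bin (period 120 s)
    2 * f[round(k)] / length(x) / mean(x)
  }, 1.0)
  expect_gt(depth[1], 5 * depth[2])
})

test_that("seeded synthesis is reproducible and seeds differ", {
  a <- synthesize_spectrum(c(holo = 0.01, tris = 1), models, supp, seed = 5)
  b <- synthesize_spectrum(c(holo = 0.01, tris = 1), models, supp, seed = 5)
  c <- synthesize_spectrum(c(holo = 0.01, tris = 1), models, supp, seed = 6)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
})
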