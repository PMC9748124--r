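test_that("the noise model is deterministic in its seed and truncated at zero", {
  v <- c(0.01, 1, 5, 100)
  n1 <- apply_noise(v, noise_spec(0.5, 0.3, seed = 4))
  n2 <- apply_noise(v, noise_spec(0.5, 0.3, seed = 4))
  n3 <- apply_noise(v, noise_spec(0.5, 0.3, seed = 5))
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  expect_true(all(n1 >= 0))
  expect_identical(apply_noise(v, noise_off()), v)
  expect_error(noise_spec(-1, 0.05), "additive_sd")
  expect_error(noise_spec(0, 1.2), "proportional_cv")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(generate_nash_cohort(10, seed = 1))
  invisible(generate_hsp_series(hsp_truth(),
                                sample_times = seq(0, 60, 20),
                                noise = noise_spec(0, 0.05, 2)))
  expect_identical(runif(1), before)
})

test_that("zero-inflow protein series is constant at basal and seeded noise repeats", {
  p0 <- hsp_params(A = 0, k1 = 0.05, k2 = 0.1, Tm = 0.5, Km = 8, cb = 2,
                   tmax = 120)
  s <- generate_hsp_series(p0, sample_times = seq(0, 120, 20),
                           noise = noise_off())
  expect_equal(s$value, rep(2, 7))
  n1 <- generate_hsp_series(hsp_truth(), noise = noise_spec(0, 0.05, 11))
  n2 <- generate_hsp_series(hsp_truth(), noise = noise_spec(0, 0.05, 11))
  expect_identical(n1$value, n2$value)
})

test_that("in the linear regime (c << Km) the protein series matches the one-compartment closed form", {
  # Km so large that elimination is linear with rate k = Tm/(V Km)
  A <- 0.3; k1 <- 0.05; k2 <- 0.08; TmV <- 2e6; Km <- 1e7; tmax <- 120
  p <- hsp_params(A = A, k1 = k1, k2 = k2, Tm = TmV, Km = Km, tmax = tmax)
  k <- TmV / Km
  tt <- seq(0, 300, 10)
  sim <- generate_hsp_series(p, sample_times = tt, noise = noise_off())
  rise <- function(t) {
    A * ((1 - exp(-k * t)) / k - (exp(-k1 * t) - exp(-k * t)) / (k - k1))
  }
  ct <- ifelse(tt <= tmax, rise(tt),
               rise(tmax) * exp(-k * (tt - tmax)) +
                 A * (exp(-k2 * (tt - tmax)) - exp(-k * (tt - tmax))) /
                 (k - k2))
  expect_equal(sim$value[-1], ct[-1], tolerance = 1e-6)
})

test_that("zero-dose antibody series is identically zero", {
  r <- generate_mab_rfu_series(tmdd_truth(), dose = 0,
                               sample_times = tmdd_grid(),
                               noise = noise_off())
  expect_equal(r$value, rep(0, length(tmdd_grid())))
})

test_that("the attached inflow profile integrates exactly to the dose", {
  r <- generate_mab_rfu_series(tmdd_truth(), dose = 200,
                               sample_times = tmdd_grid(),
                               noise = noise_off())
  prof <- attr(r, "inflow")
  expect_equal(sum(prof$rates * diff(prof$breakpoints)), 200)
})

test_that("an OGTT record with no forcing and basal insulin sits at its fixed point", {
  tt <- c(0, 20, 40, 60, 80, 100, 120, 180)
  ins <- timeseries(c(0, 180), c(100, 100), "min", "pmol/L")
  isr0 <- timeseries(c(0, 180), c(0, 0), "min", "pmol/min")
  rec <- generate_ogtt_record(mm_truth(), rat_cpk(), isr0, ins, Gb = 5.5,
                              cp_basal = 0.2, sample_times = tt,
                              noise = noise_off())
  expect_equal(rec$glucose$value, rep(5.5, 8), tolerance = 1e-8)
  expect_equal(rec$cpeptide$value, rep(0.2, 8), tolerance = 1e-10)
  # fixed seed: identical record
  r1 <- generate_ogtt_record(mm_truth(), rat_cpk(), isr_pulse(),
                             ogtt_insulin(), Gb = 5.5,
                             glucose_forcing = ogtt_forcing(),
                             noise = noise_spec(0, 0.03, 8))
  r2 <- generate_ogtt_record(mm_truth(), rat_cpk(), isr_pulse(),
                             ogtt_insulin(), Gb = 5.5,
                             glucose_forcing = ogtt_forcing(),
                             noise = noise_spec(0, 0.03, 8))
  expect_identical(r1$glucose$value, r2$glucose$value)
  expect_identical(r1$cpeptide$value, r2$cpeptide$value)
})

test_that("NASH cohorts are reproducible and recover their noise calibration", {
  c1 <- generate_nash_cohort(50, seed = 13)
  c2 <- generate_nash_cohort(50, seed = 13)
  expect_identical(c1, c2)
  # variance arithmetic: sd chosen for a target R2 gives that R2 at large n
  sd78 <- nash_noise_sd_for_r2(nas_reference_model(), c(100, 600),
                               c(100, 2000), 0.78)
  coh <- generate_nash_cohort(4000, noise_sd = sd78, seed = 17)
  expect_equal(fit_nas(coh)$r2, 0.78, tolerance = 0.05)
})
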