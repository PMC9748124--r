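test_that("allometric rules reproduce the printed percentage relationships", {
  k <- kinetics_from_body_weight(400)
  expect_equal(k$Vtot, 152)                       # 38% of 400 g
  expect_equal(k$V1, 63.84)                       # 42% of Vtot
  expect_equal(k$V1 + k$V2, k$Vtot)
  expect_equal(k$V1 / k$Vtot, 0.42)
  expect_equal(k$k01 * k$V1 / k$Vtot, 0.082)
  expect_equal(k$k21 * k$V1 / k$Vtot, 0.077)
  expect_equal(k$k12 * k$V2 / k$Vtot, 0.077)
  expect_equal(k$k01, 0.1952, tolerance = 1e-3)
  expect_equal(k$k21, 0.1833, tolerance = 1e-3)
  expect_equal(k$k12, 0.1328, tolerance = 1e-3)
  # doubling body weight doubles volumes, leaves rates unchanged
  k2 <- kinetics_from_body_weight(800)
  expect_equal(k2$V1, 2 * k$V1)
  expect_equal(k2$k01, k$k01)
})

test_that("zero secretion gives zero C-peptide; constant secretion reaches s/k01", {
  k <- rat_cpk()
  sr0 <- timeseries(c(0, 180), c(0, 0), "min", "nmol/L/min")
  expect_equal(simulate_cpeptide(k, sr0, t_grid = c(0, 60, 180))$value,
               c(0, 0, 0))
  s <- 0.5
  src <- timeseries(c(0, 600), c(s, s), "min", "nmol/L/min")
  cp <- simulate_cpeptide(k, src, t_grid = c(0, 300, 600),
                          interp = "constant")
  expect_equal(cp$value[3], s / k$k01, tolerance = 1e-6)
})

test_that("the piecewise-constant propagator matches the matrix exponential", {
  k <- rat_cpk()
  M <- matrix(c(-(k$k01 + k$k21), k$k12, k$k21, -k$k12), 2, byrow = TRUE)
  # impulse approximated by a 1-min pulse, then free decay: compare the
  # decay phase against expm(M t) applied to the state at pulse end
  sr <- timeseries(c(0, 1, 240), c(1, 0, 0), "min", "nmol/L/min")
  tg <- c(0, 1, 30, 60, 120, 240)
  cp <- simulate_cpeptide(k, sr, t_grid = tg, interp = "constant")
  # oracle state at t = 1 from the augmented exponential, then propagate
  aug <- rbind(cbind(M, c(1, 0)), 0)
  E1 <- as.matrix(Matrix::expm(aug))
  x1 <- E1[1:2, 3]
  for (i in 3:length(tg)) {
    xt <- as.matrix(Matrix::expm(M * (tg[i] - 1))) %*% x1
    expect_equal(cp$value[i], xt[1, 1], tolerance = 1e-8)
  }
})

test_that("the kinetic system is linear in the secretion input", {
  k <- rat_cpk()
  tg <- c(0, 20, 40, 60, 120, 180)
  sr1 <- timeseries(c(0, 20, 60, 180), c(0.2, 0.5, 0.1, 0), "min",
                    "nmol/L/min")
  sr2 <- timeseries(c(0, 20, 60, 180), c(0.4, 0.1, 0.3, 0), "min",
                    "nmol/L/min")
  mix <- timeseries(c(0, 20, 60, 180),
                    2 * sr1$value + 3 * sr2$value, "min", "nmol/L/min")
  a <- simulate_cpeptide(k, sr1, tg, interp = "constant")$value
  b <- simulate_cpeptide(k, sr2, tg, interp = "constant")$value
  ab <- simulate_cpeptide(k, mix, tg, interp = "constant")$value
  expect_equal(ab, 2 * a + 3 * b, tolerance = 1e-9)
})

test_that("deconvolution recovers a square-pulse secretion and its AUC", {
  k <- rat_cpk()
  ins <- timeseries(c(0, 180), c(100, 100), "min", "pmol/L")
  rec <- generate_ogtt_record(mm_truth(), k, isr_pulse(), ins, Gb = 5.5,
                              noise = noise_off())
  sp <- deconvolve_isr(rec, k, lambda_reg = 1e-8)
  true_auc <- 60 * 40                     # 60 pmol/min on [20, 60) min
  expect_lt(abs(sp$isr_auc - true_auc) / true_auc, 0.02)
  # the recovered step profile matches the pulse segment-by-segment
  expect_lt(max(abs(sp$sr * k$V1 - c(0, 60, 60, 0, 0, 0, 0, 0))),
            1e-3)
})

test_that("C-peptide flat at basal deconvolves to zero secretion", {
  k <- rat_cpk()
  tt <- c(0, 20, 40, 60, 80, 100, 120, 180)
  rec <- ogtt_record(
    glucose = timeseries(tt, rep(5.5, 8), "min", "mmol/L"),
    insulin = timeseries(tt, rep(100, 8), "min", "pmol/L"),
    cpeptide = timeseries(tt, rep(0.2, 8), "min", "nmol/L"),
    body_weight = 400)
  sp <- deconvolve_isr(rec, k, lambda_reg = 1e-6)
  expect_equal(sp$isr_auc, 0, tolerance = 1e-8)
  expect_equal(max(abs(sp$isr$value)), 0, tolerance = 1e-8)
})

test_that("ISR scales with the accessible volume while SR does not", {
  k <- rat_cpk()
  ins <- timeseries(c(0, 180), c(100, 100), "min", "pmol/L")
  rec <- generate_ogtt_record(mm_truth(), k, isr_pulse(), ins, Gb = 5.5,
                              noise = noise_off())
  k2 <- cpeptide_kinetics(k$k01, k$k21, k$k12, 2 * k$V1, k$V2)
  sp1 <- deconvolve_isr(rec, k, lambda_reg = 1e-8)
  sp2 <- deconvolve_isr(rec, k2, lambda_reg = 1e-8)
  expect_equal(sp2$sr, sp1$sr, tolerance = 1e-6)
  expect_equal(sp2$isr_auc, 2 * sp1$isr_auc, tolerance = 1e-6)
})

test_that("responsivity is the ratio of cleared C-peptide to glucose excursion", {
  # direct arithmetic: k01 = 0.2, integral CP1 = 30, integral dG = 300
  cp1 <- timeseries(c(0, 60, 120, 180), c(0, 0.25, 0.25, 0), "min", "nmol/L")
  # trapezoid of cp1: 60*0.125 + 60*0.25 + 60*0.125 = 30
  glu <- timeseries(c(0, 90, 180), c(5, 5 + 10/3, 5), "min", "mmol/L")
  # trapezoid of dG: 300
  expect_equal(phi_responsivity(cp1, glu, 5, 0.2), 0.02)
  # doubling the glucose excursion halves phi
  glu2 <- timeseries(c(0, 90, 180), c(5, 5 + 20/3, 5), "min", "mmol/L")
  expect_equal(phi_responsivity(cp1, glu2, 5, 0.2), 0.01)
  # zero C-peptide gives zero phi
  cp0 <- timeseries(c(0, 90, 180), c(0, 0, 0), "min", "nmol/L")
  expect_equal(phi_responsivity(cp0, glu, 5, 0.2), 0)
  # no glucose excursion: undefined
  flat <- timeseries(c(0, 90, 180), c(5, 5, 5), "min", "mmol/L")
  expect_error(phi_responsivity(cp1, flat, 5, 0.2), "excursion")
})
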