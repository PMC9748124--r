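# closed form of the pure-inflow phase (Tm = 0, t <= tmax):
# c(t) = (A/k1) (k1 t - 1 + e^{-k1 t})
inflow_only_closed_form <- function(A, k1, t) A / k1 * (k1 * t - 1 + exp(-k1 * t))

test_that("zero inflow gives the zero incremental curve", {
  p <- hsp_params(A = 0, k1 = 0.05, k2 = 0.03, Tm = 0.5, Km = 8, tmax = 120)
  sim <- simulate_hsp(p, seq(0, 240, 10))
  expect_equal(sim$value, rep(0, length(sim$time)))
})

test_that("with no elimination the rise phase matches its symbolic integral", {
  p <- hsp_params(A = 0.3, k1 = 0.04, k2 = 0.05, Tm = 0, Km = 8, tmax = 120)
  tt <- seq(0, 120, 5)
  sim <- simulate_hsp(p, tt)
  expected <- inflow_only_closed_form(0.3, 0.04, tt)
  expect_equal(sim$value[-1], expected[-1], tolerance = 1e-8)
})

test_that("small-concentration washout decays at the linear-limit rate Tm/(V Km)", {
  # c << Km throughout; log-linear slope of the tail ~ -Tm/(V*Km)
  p <- hsp_params(A = 0, k1 = 0.05, k2 = 1, V = 40, Tm = 5, Km = 10,
                  tmax = 10)
  sim <- simulate_hsp(p, seq(0, 240, 2), c0 = 0.05)
  tail_idx <- sim$time >= 20
  slope <- unname(coef(lm(log(sim$value[tail_idx]) ~ sim$time[tail_idx]))[2])
  expect_equal(-slope, 5 / (40 * 10), tolerance = 0.01)
})

test_that("simulation agrees with an independent fixed-step integrator", {
  p <- hsp_truth()
  tt <- seq(0, 360, 20)
  sim <- simulate_hsp(p, tt)
  # independent oracle: classical RK4 at h = 0.05 min, implemented inline
  h <- 0.05
  rhs <- function(t, c) {
    infl <- if (t <= p$tmax) p$A * (1 - exp(-p$k1 * t)) else
      p$A * exp(-p$k2 * (t - p$tmax))
    infl - (p$Tm / p$V) * c / (p$Km + c)
  }
  y <- 0; tcur <- 0; out <- numeric(length(tt)); out[1] <- 0
  for (i in 2:length(tt)) {
    while (tcur < tt[i] - 1e-9) {
      k1s <- rhs(tcur, y); k2s <- rhs(tcur + h/2, y + h/2 * k1s)
      k3s <- rhs(tcur + h/2, y + h/2 * k2s); k4s <- rhs(tcur + h, y + h * k3s)
      y <- y + h/6 * (k1s + 2*k2s + 2*k3s + k4s); tcur <- tcur + h
    }
    out[i] <- y
  }
  expect_equal(sim$value[-1], out[-1], tolerance = 1e-6)
})

test_that("elimination stays bounded and the curve stays non-negative across a parameter box", {
  set.seed(42)
  for (i in 1:12) {
    p <- hsp_params(A = runif(1, 0, 0.6), k1 = runif(1, 0.01, 0.2),
                    k2 = runif(1, 0.01, 0.3), Tm = runif(1, 0.05, 1),
                    Km = runif(1, 1, 20), tmax = sample(c(60, 120, 180), 1))
    sim <- simulate_hsp(p, seq(0, 300, 10))
    expect_true(all(sim$value >= 0))
  }
})

test_that("noise-free fitting recovers the generating parameters", {
  obs <- generate_hsp_series(hsp_truth(), sample_times = hsp_grid(),
                             noise = noise_off())
  fit <- fit_hsp(obs, hsp_init())
  truth <- c(A = 0.4, k1 = 0.05, k2 = 0.1, TmV = 0.5, Km = 8)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates[names(truth)] - truth) / truth), 0.01)
})

test_that("a record flat at basal drives the inflow estimate to zero", {
  flat <- timeseries(seq(0, 240, 20), rep(2, 13), "min", "ng/mL", basal = 2)
  fit <- fit_hsp(flat, hsp_init())
  expect_equal(unname(fit$estimates[["A"]]), 0, tolerance = 1e-6)
})

test_that("curve-based half-life matches closed forms", {
  # exponential decay from the first sample at rate 0.0125/min
  tt <- seq(0, 240, 5)
  ex <- timeseries(tt, 10 * exp(-0.0125 * tt), "min", "ng/mL")
  expect_equal(half_life(ex)$value, log(2) / 0.0125, tolerance = 0.01)
  # triangular curve: peak 10 at t = 60, value 5 at t = 90
  tri <- timeseries(c(0, 60, 90), c(0, 10, 5), "min", "ng/mL")
  expect_equal(half_life(tri)$value, 30)
  # curve never reaching half-maximum
  shallow <- timeseries(c(0, 60, 120), c(0, 10, 8), "min", "ng/mL")
  expect_error(half_life(shallow), "never falls")
})

test_that("half-life in the linear limit equals ln2 V Km / Tm", {
  p <- hsp_params(A = 0, k1 = 0.05, k2 = 1, V = 40, Tm = 5, Km = 10,
                  tmax = 10)
  sim <- simulate_hsp(p, seq(0, 240, 1), c0 = 0.1)
  expect_equal(half_life(sim)$value, log(2) * 40 * 10 / 5, tolerance = 0.02)
})

test_that("shrinking Km at fixed Tm/Km leaves the small-c decay rate unchanged", {
  slope_of <- function(Tm, Km) {
    p <- hsp_params(A = 0, k1 = 0.05, k2 = 1, V = 1, Tm = Tm, Km = Km,
                    tmax = 10)
    sim <- simulate_hsp(p, seq(0, 100, 2), c0 = Km / 1000)
    idx <- sim$time >= 10
    unname(coef(lm(log(sim$value[idx]) ~ sim$time[idx]))[2])
  }
  expect_equal(slope_of(0.5, 10), slope_of(0.05, 1), tolerance = 1e-3)
})
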