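#' Parameters of the serum HSP70/GRP78 kinetic model
#'
#' One-compartment model of the incremental (above-basal) serum concentration
#' `c(t)` of a gut-secreted chaperone during an inflow phase and washout:
#' \deqn{dc/dt = A (1 - e^{-k_1 t}) - (1/V)\, T_m c / (K_m + c), \quad t \le t_{max}}
#' \deqn{dc/dt = A e^{-k_2 (t - t_{max})} - (1/V)\, T_m c / (K_m + c), \quad t > t_{max}}
#' with `c(0) = 0`. The inflow term is the subcutaneous infusion of the
#' recombinant protein (rats) or the meal-stimulated gut secretion of the
#' native protein (rats and humans); the Michaelis-Menten term is
#' receptor-mediated tissue uptake.
#'
#' Concentration data constrain only the ratio `Tm/V` (the elimination term
#' is `(Tm/V) c/(Km+c)`), so `V` defaults to 1 mL, making `Tm` numerically
#' equal to the identifiable clearance-capacity ratio `Tm/V` in
#' ng/(mL min). Supply a measured `V` to report `Tm` on its natural scale.
#'
#' @param A maximal inflow rate, ng/(mL min).
#' @param k1 rate of inflow increase, 1/min.
#' @param k2 rate of inflow decrease after `tmax`, 1/min.
#' @param V plasma distribution volume, mL (default 1, see above).
#' @param Tm maximal elimination rate, ng/min.
#' @param Km half-saturation concentration, ng/mL.
#' @param cb constant basal concentration, ng/mL.
#' @param tmax time of maximal measured concentration, min. Fixed from the
#'   data before any fitting, never estimated.
#'
#' @return an object of class `hsp_params`.
#' @export
hsp_params <- function(A, k1, k2, V = 1, Tm, Km, cb = 0, tmax) {
  p <- list(A = A, k1 = k1, k2 = k2, V = V, Tm = Tm, Km = Km,
            cb = cb, tmax = tmax)
  for (nm in c("A", "k1", "k2", "V", "Tm", "Km", "cb")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("`%s` must be finite and >= 0", nm), call. = FALSE)
    }
  }
  if (!is.finite(tmax) || tmax <= 0) stop("`tmax` must be > 0", call. = FALSE)
  if (p$V == 0) stop("`V` must be > 0", call. = FALSE)
  structure(p, class = "hsp_params")
}

# inflow rate at time t (vectorized)
hsp_inflow <- function(t, p) {
  ifelse(t <= p$tmax,
         p$A * (1 - exp(-p$k1 * t)),
         p$A * exp(-p$k2 * (t - p$tmax)))
}

# Michaelis-Menten elimination rate, guarded at Km = c = 0
mm_elim <- function(c, TmV, Km) {
  ifelse(Km + c > 0, TmV * c / (Km + c), 0)
}

#' Simulate the incremental HSP concentration curve
#'
#' Integrates the two-phase model with a stiff-capable adaptive method
#' (deSolve lsoda, rtol 1e-10 / atol 1e-12 ng/mL), splitting the integration
#' at `tmax` where the inflow switches branch.
#'
#' @param params an [hsp_params()] object.
#' @param t_grid increasing output times (min) starting at 0.
#' @param c0 initial incremental concentration (ng/mL), 0 in the model as
#'   stated; settable to start a washout-only simulation from a loaded state.
#' @return a [timeseries()] of the incremental concentration `c(t)` (basal
#'   excluded), guaranteed non-negative.
#' @export
simulate_hsp <- function(params, t_grid, c0 = 0) {
  stopifnot(inherits(params, "hsp_params"))
  t_grid <- as.numeric(t_grid)
  if (t_grid[1L] != 0) stop("`t_grid` must start at 0", call. = FALSE)
  if (any(diff(t_grid) <= 0)) stop("`t_grid` must be increasing", call. = FALSE)
  TmV <- params$Tm / params$V
  A <- params$A; k1 <- params$k1; k2 <- params$k2
  Km <- params$Km; tmax <- params$tmax
  rhs <- function(t, y, parms) {
    infl <- if (t <= tmax) A * (1 - exp(-k1 * t)) else
      A * exp(-k2 * (t - tmax))
    cc <- if (y[1L] > 0) y[1L] else 0
    elim <- if (Km + cc > 0) TmV * cc / (Km + cc) else 0
    list(infl - elim)
  }
  c_out <- ode_split(rhs, c0, t_grid, split_at = params$tmax,
                     label = "HSP kinetics")
  timeseries(t_grid, pmax(c_out, 0), "min", "ng/mL", basal = params$cb)
}

# Integrate a scalar ODE with output at t_grid, splitting the interval at
# `split_at` (an inflow discontinuity/kink). Retries at looser tolerance
# when the stepper stalls (keeps least-squares surfaces free of cliffs for
# pathological trial parameters); fails hard only when both attempts do.
ode_split <- function(rhs, y0, t_grid, split_at = NULL, label = "model") {
  times <- t_grid
  knots <- sort(unique(c(times, split_at[split_at > min(times) &
                                           split_at < max(times)])))
  attempt <- function(rtol, atol, maxsteps) {
    try(suppressWarnings(
      deSolve::lsoda(y = c(c = y0), times = knots, func = rhs,
                     parms = NULL, rtol = rtol, atol = atol,
                     maxsteps = maxsteps)), silent = TRUE)
  }
  sol <- attempt(1e-10, 1e-12, 5000)
  if (inherits(sol, "try-error") || nrow(sol) < length(knots)) {
    # stiff/pathological trial parameters: fall back to a fixed-step RK4
    # sweep, which always completes and keeps the objective surface smooth
    vals <- rk4_sweep(rhs, y0, knots, n_steps = 2000L)
    if (anyNA(vals) || any(!is.finite(vals))) {
      stop(sprintf("%s: non-finite state in fallback integration", label),
           call. = FALSE)
    }
    return(vals[match(times, knots)])
  }
  vals <- sol[, 2L]
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals))[1L]
    stop(sprintf("%s: non-finite state at t = %g", label, sol[bad, 1L]),
         call. = FALSE)
  }
  vals[match(times, sol[, 1L])]
}

# classical RK4 with a fixed number of sub-steps spread over the knot
# spans; output at the knots
rk4_sweep <- function(rhs, y0, knots, n_steps = 4000L) {
  span <- diff(range(knots))
  out <- numeric(length(knots))
  out[1L] <- y <- y0
  for (k in seq_len(length(knots) - 1L)) {
    h_total <- knots[k + 1L] - knots[k]
    n <- max(2L, ceiling(n_steps * h_total / span))
    h <- h_total / n
    t <- knots[k]
    for (i in seq_len(n)) {
      k1 <- rhs(t, y, NULL)[[1L]]
      k2 <- rhs(t + h / 2, y + h / 2 * k1, NULL)[[1L]]
      k3 <- rhs(t + h / 2, y + h / 2 * k2, NULL)[[1L]]
      k4 <- rhs(t + h, y + h * k3, NULL)[[1L]]
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!is.finite(y)) return(rep(NA_real_, length(knots)))
      t <- t + h
    }
    out[k + 1L] <- y
  }
  out
}

#' Fit the HSP kinetic model to a measured serum curve
#'
#' Ordinary (unweighted) least squares of `c(t) + cb` against the measured
#' total concentrations. `tmax` is fixed at the time of the maximal measured
#' value, and `cb` at the pre-dose (t = 0) measurement, before optimization.
#' The estimated parameters are `A`, `k1`, `k2`, the identifiable clearance
#' ratio `TmV = Tm/V`, and `Km`; `V` can be fixed by the user via `V`, in
#' which case `Tm = TmV * V` is also reported.
#'
#' @param observed a [timeseries()] of total measured concentration (basal
#'   included), >= 6 points spanning rise and decay.
#' @param init an [hsp_params()] with starting values.
#' @param lower,upper optional named bounds on `(A, k1, k2, TmV, Km)`;
#'   defaults: all >= 0, no upper bound.
#' @param V optional measured distribution volume (mL) used only to convert
#'   `TmV` back to `Tm`.
#' @param weights optional per-point weights for a weighted fit; default
#'   `NULL` means the ordinary unweighted objective.
#' @return a [fit_result()]; non-convergence sets the flag, no exception.
#' @export
fit_hsp <- function(observed, init, lower = NULL, upper = NULL, V = NULL,
                    weights = NULL) {
  stopifnot(inherits(observed, "gutpk_ts"))
  if (length(observed$time) < 6L) {
    stop("need >= 6 observations spanning rise and decay", call. = FALSE)
  }
  cb <- if (!is.na(observed$basal)) observed$basal else observed$value[1L]
  tmax <- ts_peak(observed)$tmax
  # a record peaking at t = 0 (e.g. flat at basal) has no descent phase;
  # place the inflow switch at the end of the record
  if (tmax <= 0) tmax <- observed$time[length(observed$time)]
  t_grid <- observed$time
  if (t_grid[1L] != 0) stop("observed record must start at t = 0", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(t_grid)) else sqrt(weights)

  par0 <- c(A = init$A, k1 = init$k1, k2 = init$k2,
            TmV = init$Tm / init$V, Km = init$Km)
  lo <- c(A = 0, k1 = 0, k2 = 0, TmV = 0, Km = 0)
  hi <- c(A = Inf, k1 = Inf, k2 = Inf, TmV = Inf, Km = Inf)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  resid_fn <- function(par) {
    p <- hsp_params(A = par[["A"]], k1 = par[["k1"]], k2 = par[["k2"]],
                    V = 1, Tm = par[["TmV"]], Km = par[["Km"]],
                    cb = cb, tmax = tmax)
    sim <- try(simulate_hsp(p, t_grid), silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e6, length(t_grid)))
    w * (sim$value + cb - observed$value)
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lo, upper = hi,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  est <- fit$par
  se <- se_from_nlslm(fit, length(est))
  names(se) <- names(est)
  fixed <- list(cb = cb, tmax = tmax)
  if (!is.null(V)) {
    est <- c(est, Tm = unname(est[["TmV"]] * V))
    se <- c(se, Tm = unname(se[["TmV"]] * V))
    fixed$V <- V
  }
  fit_result(estimates = est, std_errors = se, residuals = fit$fvec,
             objective = fit$deviance,
             converged = fit$info %in% 1:3,
             message = fit$message, fixed = fixed)
}

#' Curve-based half-life
#'
#' The half-life is read off the curve: the time interval between the time
#' of maximal incremental concentration and the (linearly interpolated) time
#' at which the incremental concentration first falls to half of its maximum
#' on the descending branch.
#'
#' @param curve a [timeseries()] of incremental (basal-subtracted)
#'   concentration with a maximum inside the record.
#' @return list with `value` (half-life, in `curve$time_unit`) and
#'   `method = "curve-based"`.
#' @export
half_life <- function(curve) {
  stopifnot(inherits(curve, "gutpk_ts"))
  pk <- ts_peak(curve)
  if (pk$cmax <= 0) stop("curve has no positive maximum", call. = FALSE)
  half <- pk$cmax / 2
  tt <- curve$time[pk$index:length(curve$time)]
  yy <- curve$value[pk$index:length(curve$value)]
  below <- which(yy <= half)
  if (!length(below)) {
    stop("incremental concentration never falls to half of its maximum ",
         "within the record", call. = FALSE)
  }
  j <- below[1L]
  if (j == 1L) {
    t_half <- tt[1L]
  } else {
    # linear interpolation between the bracketing samples
    t_half <- tt[j - 1L] + (half - yy[j - 1L]) *
      (tt[j] - tt[j - 1L]) / (yy[j] - yy[j - 1L])
  }
  list(value = t_half - pk$tmax, method = "curve-based",
       unit = curve$time_unit)
}
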