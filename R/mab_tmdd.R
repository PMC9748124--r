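#' Parameters of the QSS target-mediated disposition model for anti-HSP mAbs
#'
#' One-compartment model for a monoclonal antibody injected subcutaneously
#' (dose `D`, pmol) that binds its circulating target (total concentration
#' `Pbar`, held constant). Under the quasi-steady-state (QSS) approximation
#' the fast binding dynamics collapse to an algebraic partition of total
#' antibody `At` into free `A` and complex `B`:
#' \deqn{B = \bar P A / (K_{SS} + A), \qquad K_{SS} = (k_{off} + k_{int})/k_{on}}
#' and the total concentration obeys
#' \deqn{dA_t/dt = I(t)/V - k_e A - k_{int} \bar P A / (K_{SS} + A), \ A_t(0)=0.}
#' Fluorescence readings are proportional to `At` with constant `K`.
#'
#' @param V compartment volume, L.
#' @param ke free-antibody elimination rate, 1/h.
#' @param kint complex internalization rate, 1/h.
#' @param KSS quasi-steady-state dissociation constant, pM.
#' @param K fluorescence proportionality constant, RFU/pM.
#' @param Pbar constant total target concentration, pM.
#' @param D injected dose, pmol.
#' @param kon,koff optional explicit binding rates (1/(pM h), 1/h) for the
#'   full (non-QSS) binding model; when both are given together with `kint`,
#'   the identity `KSS = (koff + kint)/kon` must hold to 1e-9 relative.
#'
#' @return an object of class `tmdd_params`.
#' @export
tmdd_params <- function(V, ke, kint, KSS, K = 1, Pbar = 0, D = 0,
                        kon = NULL, koff = NULL) {
  p <- list(V = V, ke = ke, kint = kint, KSS = KSS, K = K, Pbar = Pbar,
            D = D, kon = kon, koff = koff)
  for (nm in c("V", "ke", "kint", "KSS", "K", "Pbar", "D")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("`%s` must be finite and >= 0", nm), call. = FALSE)
    }
  }
  if (V == 0) stop("`V` must be > 0", call. = FALSE)
  if (!is.null(kon) && !is.null(koff)) {
    kss_implied <- (koff + kint) / kon
    if (abs(kss_implied - KSS) > 1e-9 * max(KSS, kss_implied)) {
      stop("inconsistent binding constants: KSS != (koff + kint)/kon",
           call. = FALSE)
    }
  }
  structure(p, class = "tmdd_params")
}

#' Free antibody concentration under the QSS partition
#'
#' Non-negative root of `(At - A)(KSS + A) = Pbar * A`:
#' \deqn{A = \tfrac12\left[(A_t - \bar P - K_{SS}) +
#'   \sqrt{(A_t - \bar P - K_{SS})^2 + 4 A_t K_{SS}}\right]}
#' evaluated in a cancellation-safe form: when `At - Pbar - KSS < 0` the
#' conjugate expression `2 At KSS / (sqrt(disc) - b)` is used.
#'
#' @param At total antibody concentration, pM (vectorized).
#' @param Pbar total target concentration, pM.
#' @param KSS QSS dissociation constant, pM.
#' @return free antibody concentration `A`, pM.
#' @export
free_mab <- function(At, Pbar, KSS) {
  stopifnot(all(At >= 0), Pbar >= 0, KSS >= 0)
  b <- At - Pbar - KSS
  disc <- sqrt(b^2 + 4 * At * KSS)
  ifelse(b < 0,
         ifelse(disc - b > 0, 2 * At * KSS / (disc - b), 0),
         (b + disc) / 2)
}

#' Bound (complex) concentration under the QSS partition
#'
#' `B = Pbar * A / (KSS + A)`; with `A` from [free_mab()] the partition
#' conserves mass, `A + B = At`, to floating tolerance.
#'
#' @param A free antibody concentration, pM (vectorized).
#' @inheritParams free_mab
#' @return complex concentration `B`, pM.
#' @export
bound_complex <- function(A, Pbar, KSS) {
  stopifnot(all(A >= 0), Pbar >= 0, KSS >= 0)
  ifelse(KSS + A > 0, Pbar * A / (KSS + A), 0)
}

#' Piecewise-constant subcutaneous inflow profile
#'
#' @param breakpoints increasing times (h) delimiting the intervals.
#' @param rates inflow rate (pmol/h) on each interval,
#'   `length(breakpoints) - 1` values, all >= 0. Inflow is zero after the
#'   last breakpoint.
#' @return an object of class `inflow_profile`.
#' @export
inflow_profile <- function(breakpoints, rates) {
  breakpoints <- as.numeric(breakpoints)
  rates <- as.numeric(rates)
  stopifnot(length(rates) == length(breakpoints) - 1L,
            all(diff(breakpoints) > 0), all(rates >= 0))
  structure(list(breakpoints = breakpoints, rates = rates),
            class = "inflow_profile")
}

# inflow rate at time t (vectorized; zero outside the breakpoints)
inflow_rate <- function(profile, t) {
  idx <- findInterval(t, profile$breakpoints,
                      left.open = FALSE, rightmost.closed = TRUE)
  r <- rep(0, length(t))
  inside <- idx >= 1L & idx <= length(profile$rates)
  r[inside] <- profile$rates[idx[inside]]
  r
}

# total mass delivered by a profile
inflow_total <- function(profile) {
  sum(profile$rates * diff(profile$breakpoints))
}

#' Reconstruct the subcutaneous inflow from fluorescence AUC ratios
#'
#' Absorption from the subcutaneous depot is represented as biphasic: half
#' of the dose `D` enters the blood between 0 and `t_peak` (the time of
#' maximal concentration) and the other half between `t_peak` and the end of
#' the record. Within each half, the inflow is piecewise constant on the
#' sampling intervals, with per-interval masses proportional to the
#' trapezoidal fluorescence AUC of that interval:
#' `AUC(I)_interval / AUC(I)_half = AUC(RFU)_interval / AUC(RFU)_half`,
#' scaled so each half integrates to `D/2`.
#'
#' @param rfu a [timeseries()] of fluorescence (>= 0) whose sampling times
#'   define the interval breakpoints; must include `t_peak`.
#' @param D injected dose, pmol.
#' @param t_peak time of maximal concentration, h (default 2 h = 120 min).
#' @return an [inflow_profile()] whose total mass is exactly `D`.
#' @export
reconstruct_inflow <- function(rfu, D, t_peak = 2) {
  stopifnot(inherits(rfu, "gutpk_ts"), D >= 0)
  t <- rfu$time; y <- rfu$value
  if (any(y < 0)) stop("RFU values must be >= 0", call. = FALSE)
  if (!any(abs(t - t_peak) < 1e-9)) {
    stop("`t_peak` must be one of the RFU sampling times", call. = FALSE)
  }
  seg_auc <- diff(t) * (y[-length(y)] + y[-1L]) / 2
  first <- which(t[-1L] <= t_peak + 1e-9)   # segments ending at or before t_peak
  second <- setdiff(seq_along(seg_auc), first)
  rates <- numeric(length(seg_auc))
  for (half in list(first, second)) {
    if (!length(half)) next
    tot <- sum(seg_auc[half])
    if (tot <= 0) {
      stop("all-zero fluorescence within one absorption half: ",
           "inflow profile is degenerate", call. = FALSE)
    }
    mass <- D / 2 * seg_auc[half] / tot
    rates[half] <- mass / diff(t)[half]
  }
  inflow_profile(t, rates)
}

#' Simulate the total antibody concentration under the QSS model
#'
#' Integrates `dAt/dt = I(t)/V - ke A - kint Pbar A/(KSS + A)`, with the
#' free concentration `A` obtained from [free_mab()] at every step. The
#' integration is split at every inflow breakpoint.
#'
#' @param params a [tmdd_params()].
#' @param inflow an [inflow_profile()] (pmol/h).
#' @param t_grid increasing output times (h) starting at 0.
#' @return a [timeseries()] of total antibody concentration `At` (pM).
#' @export
simulate_total_mab <- function(params, inflow, t_grid) {
  stopifnot(inherits(params, "tmdd_params"), inherits(inflow, "inflow_profile"))
  t_grid <- as.numeric(t_grid)
  if (t_grid[1L] != 0) stop("`t_grid` must start at 0", call. = FALSE)
  # integrate in free-antibody space: At = A + Pbar A/(KSS + A) is smooth
  # and strictly increasing in A, so
  # dA/dt = (dAt/dt) / (1 + Pbar KSS/(KSS + A)^2), which avoids the
  # quadratic-partition kink that makes the At-space ODE stiff
  P <- params$Pbar; KSS <- params$KSS
  V <- params$V; ke <- params$ke; kint <- params$kint
  brk <- inflow$breakpoints; rates <- inflow$rates; nr <- length(rates)
  rhs <- function(t, y, parms) {
    A <- if (y[1L] > 0) y[1L] else 0
    i <- findInterval(t, brk, rightmost.closed = TRUE)
    I <- if (i >= 1L && i <= nr) rates[i] else 0
    B <- if (KSS + A > 0) P * A / (KSS + A) else 0
    dAt <- I / V - ke * A - kint * B
    jac <- 1 + if (KSS + A > 0) P * KSS / (KSS + A)^2 else 0
    list(dAt / jac)
  }
  brk <- inflow$breakpoints
  A_vals <- ode_split(rhs, 0, t_grid,
                      split_at = brk[brk > 0 & brk < max(t_grid)],
                      label = "TMDD model")
  A_vals <- pmax(A_vals, 0)
  At_vals <- A_vals + bound_complex(A_vals, P, KSS)
  timeseries(t_grid, At_vals, "h", "pM")
}

#' Simulate the full (explicit-binding) antibody model
#'
#' Reference two-state model with explicit association/dissociation,
#' \deqn{dA/dt = I(t)/V - k_{on} A P + k_{off} B - k_e A}
#' \deqn{dB/dt = k_{on} A P - (k_{off} + k_{int}) B}
#' with `P = Pbar - B`. The QSS model is its limit as `kon` grows at fixed
#' `KSS`; this simulator exists to verify that convergence.
#'
#' @inheritParams simulate_total_mab
#' @param kon association rate, 1/(pM h); `koff` is derived as
#'   `kon * KSS - kint` and must be >= 0.
#' @return a [timeseries()] of total antibody `At = A + B` (pM).
#' @export
simulate_mab_full <- function(params, inflow, t_grid, kon) {
  stopifnot(inherits(params, "tmdd_params"))
  koff <- kon * params$KSS - params$kint
  if (koff < 0) stop("kon too small: koff = kon*KSS - kint < 0", call. = FALSE)
  t_grid <- as.numeric(t_grid)
  rhs <- function(t, y, parms) {
    A <- max(y[1L], 0); B <- max(y[2L], 0)
    P <- max(params$Pbar - B, 0)
    dA <- inflow_rate(inflow, t) / params$V - kon * A * P + koff * B -
      params$ke * A
    dB <- kon * A * P - (koff + params$kint) * B
    list(c(dA, dB))
  }
  brk <- inflow$breakpoints
  knots <- sort(unique(c(t_grid, brk[brk > 0 & brk < max(t_grid)])))
  sol <- deSolve::lsoda(y = c(A = 0, B = 0), times = knots, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  keep <- match(t_grid, sol[, 1L])
  timeseries(t_grid, pmax(sol[keep, "A"] + sol[keep, "B"], 0), "h", "pM")
}

#' Fit the QSS TMDD model to a fluorescence time course
#'
#' Least-squares fit of `K * At(t; V, ke, kint, KSS)` to the measured RFU
#' curve. By default the inflow profile is reconstructed from the same RFU
#' record via [reconstruct_inflow()] (and held fixed during optimization);
#' a known profile can be supplied instead via `inflow`, e.g. in recovery
#' studies where the generating inflow is available. `Pbar` is set to the
#' target concentration measured before antibody delivery. When `Pbar = 0`
#' the model reduces to linear PK and `kint`, `KSS` are structurally
#' unidentifiable: they are held at their initial values and flagged.
#'
#' @param rfu a [timeseries()] of fluorescence spanning rise and descent.
#' @param Pbar pre-dose target concentration, pM.
#' @param D injected dose, pmol.
#' @param init a [tmdd_params()] with starting values (including `K`).
#' @param t_peak absorption switch time passed to [reconstruct_inflow()].
#' @param offset logical: estimate a constant fluorescence background as a
#'   nuisance parameter (default `FALSE`, background assumed zero).
#' @param inflow optional known [inflow_profile()]; `NULL` reconstructs it
#'   from the RFU record.
#' @param starts number of deterministic multistart points (1-3); use 1 for
#'   batch Monte-Carlo studies where speed matters.
#' @return a [fit_result()] over `(V, ke, kint, KSS, K)`.
#' @export
fit_tmdd <- function(rfu, Pbar, D, init, t_peak = 2, offset = FALSE,
                     inflow = NULL, starts = 3L) {
  stopifnot(inherits(rfu, "gutpk_ts"))
  if (is.null(inflow)) inflow <- reconstruct_inflow(rfu, D, t_peak = t_peak)
  t_grid <- rfu$time
  if (t_grid[1L] != 0) {
    t_grid <- c(0, t_grid)
    obs_idx <- seq_along(rfu$time) + 1L
  } else obs_idx <- seq_along(rfu$time)

  linear_pk <- Pbar == 0
  free_names <- if (linear_pk) c("V", "ke", "K") else
    c("V", "ke", "kint", "KSS", "K")
  full0 <- c(V = init$V, ke = init$ke, kint = init$kint, KSS = init$KSS,
             K = init$K)
  par0 <- full0[free_names]
  scale <- pmax(abs(par0), 1e-8)      # optimize on a unit scale
  if (offset) { par0 <- c(par0, bg = 0); scale <- c(scale, bg = 1) }

  make_params <- function(par) {
    tmdd_params(V = par[["V"]], ke = par[["ke"]],
                kint = if (linear_pk) init$kint else par[["kint"]],
                KSS = if (linear_pk) init$KSS else par[["KSS"]],
                K = par[["K"]], Pbar = Pbar, D = D)
  }
  resid_fn <- function(par_s) {
    par <- par_s * scale
    p <- try(make_params(par), silent = TRUE)
    if (inherits(p, "try-error")) return(rep(1e6, length(obs_idx)))
    sim <- try(simulate_total_mab(p, inflow, t_grid), silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e6, length(obs_idx)))
    bg <- if (offset) par[["bg"]] else 0
    p$K * sim$value[obs_idx] + bg - rfu$value
  }
  # V, KSS and K are structurally positive (V = 0 or KSS = 0 degenerate the
  # model); keep them >= 0.1% of their initial guess
  lo <- stats::setNames(rep(0, length(par0)), names(par0))
  lo[names(lo) %in% c("V", "KSS", "K")] <- 1e-3
  if (offset) lo["bg"] <- -Inf
  ctrl <- minpack.lm::nls.lm.control(maxiter = 150, maxfev = 2000,
                                     ftol = 1e-12, ptol = 1e-12,
                                     gtol = 0, epsfcn = 1e-6)
  # deterministic multistart: the sloppy (kint, KSS) direction can strand a
  # single LM run in a shallow local minimum
  starts <- list(par0 / scale,
                 par0 / scale * 0.7,
                 par0 / scale * 1.4)[seq_len(max(1L, min(3L, starts)))]
  good_enough <- function(f) f$deviance < 1e-14 * sum(rfu$value^2)
  fit <- NULL
  for (s in starts) {
    cand <- minpack.lm::nls.lm(par = s, lower = lo, fn = resid_fn,
                               control = ctrl)
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
    if (good_enough(fit)) break
  }
  if (!good_enough(fit)) {
    # polish with a coarser finite-difference step (more robust Jacobian in
    # the flat valley), then refine again
    for (eps in c(1e-4, 1e-6)) {
      ctrl2 <- ctrl; ctrl2$epsfcn <- eps
      cand <- minpack.lm::nls.lm(par = fit$par, lower = lo, fn = resid_fn,
                                 control = ctrl2)
      if (cand$deviance < fit$deviance) fit <- cand
    }
  }
  est <- fit$par * scale
  se <- se_from_nlslm(fit, length(fit$par)) * scale
  names(se) <- names(est)
  flags <- character()
  fixed <- list(Pbar = Pbar, D = D, t_peak = t_peak)
  if (linear_pk) {
    flags <- c("unidentifiable:kint", "unidentifiable:KSS")
    fixed$kint <- init$kint
    fixed$KSS <- init$KSS
  }
  fit_result(estimates = est, std_errors = se, residuals = fit$fvec,
             objective = fit$deviance, converged = fit$info %in% 1:3,
             message = fit$message, fixed = fixed, flags = flags)
}

#' Half-life from the descending branch of a concentration curve
#'
#' Log-linear regression of the post-peak samples; the half-life is
#' `ln 2 / |slope|`.
#'
#' @param series a [timeseries()] with an interior maximum and at least 3
#'   positive post-peak samples.
#' @return list with `value` (in `series$time_unit`), `slope` (1/time unit)
#'   and `method = "log-linear"`.
#' @export
half_life_descending <- function(series) {
  stopifnot(inherits(series, "gutpk_ts"))
  pk <- ts_peak(series)
  idx <- seq(pk$index, length(series$time))
  tt <- series$time[idx]; yy <- series$value[idx]
  pos <- yy > 0
  if (sum(pos) < 3L) {
    stop("need at least 3 positive post-peak samples", call. = FALSE)
  }
  fit <- stats::lm(log(yy[pos]) ~ tt[pos])
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    stop("descending branch has non-negative log-slope: half-life undefined",
         call. = FALSE)
  }
  list(value = log(2) / abs(slope), slope = slope, method = "log-linear",
       unit = series$time_unit)
}
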