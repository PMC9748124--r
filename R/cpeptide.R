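#' Two-compartment C-peptide kinetic parameters
#'
#' Linear kinetics of C-peptide above basal,
#' \deqn{dCP_1/dt = -(k_{01} + k_{21}) CP_1 + k_{12} CP_2 + SR(t), \ CP_1(0)=0}
#' \deqn{dCP_2/dt = k_{21} CP_1 - k_{12} CP_2, \ CP_2(0)=0}
#' where `CP1`/`CP2` (nmol/L) are the accessible and peripheral
#' concentrations and `SR` is pancreatic secretion above basal normalized by
#' the accessible volume `V1`.
#'
#' @param k01 irreversible loss from the accessible compartment, 1/min.
#' @param k21,k12 exchange rates, 1/min.
#' @param V1,V2 compartment volumes, mL.
#' @return an object of class `cpeptide_kinetics`.
#' @export
cpeptide_kinetics <- function(k01, k21, k12, V1, V2) {
  p <- list(k01 = k01, k21 = k21, k12 = k12, V1 = V1, V2 = V2)
  for (nm in names(p)) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("`%s` must be finite and >= 0", nm), call. = FALSE)
    }
  }
  p$Vtot <- V1 + V2
  structure(p, class = "cpeptide_kinetics")
}

#' Allometric C-peptide kinetics from body weight
#'
#' Rodent allometric rules: `Vtot = 38%` of body weight (mL per g),
#' `V1 = 42%` of `Vtot`, `k01 = 8.2%` of `Vtot/V1`, `k21 = 7.7%` of
#' `Vtot/V1`, `k12 = 7.7%` of `Vtot/V2`, all per minute.
#'
#' @param body_weight body weight in grams.
#' @return a [cpeptide_kinetics()].
#' @export
kinetics_from_body_weight <- function(body_weight) {
  if (!is.finite(body_weight) || body_weight <= 0) {
    stop("`body_weight` must be > 0", call. = FALSE)
  }
  Vtot <- 0.38 * body_weight
  V1 <- 0.42 * Vtot
  V2 <- Vtot - V1
  cpeptide_kinetics(k01 = 0.082 * Vtot / V1,
                    k21 = 0.077 * Vtot / V1,
                    k12 = 0.077 * Vtot / V2,
                    V1 = V1, V2 = V2)
}

# system matrix of the two-compartment model
cp_matrix <- function(kin) {
  matrix(c(-(kin$k01 + kin$k21), kin$k12,
           kin$k21, -kin$k12), nrow = 2L, byrow = TRUE)
}

# Exact propagation over one step of length h with constant input (s, 0):
# augmented matrix exponential handles singular system matrices too.
cp_step <- function(M, x, s, h) {
  Aug <- rbind(cbind(M * h, c(s * h, 0)), 0)
  E <- as.matrix(Matrix::expm(Aug))
  as.numeric(E[1:2, 1:2] %*% x + E[1:2, 3L])
}

#' Simulate accessible-compartment C-peptide from a secretion profile
#'
#' @param kin a [cpeptide_kinetics()].
#' @param sr a [timeseries()] of above-basal secretion `SR(t)`
#'   (nmol/L/min, already normalized by `V1`).
#' @param t_grid output times (min); defaults to the secretion times.
#' @param interp `"constant"` treats `sr` as piecewise constant on its
#'   sampling intervals (left value holds; zero after the record) and uses
#'   the exact matrix-exponential propagator; `"linear"` interpolates
#'   linearly and integrates adaptively.
#' @return a [timeseries()] of `CP1` (nmol/L above basal).
#' @export
simulate_cpeptide <- function(kin, sr, t_grid = sr$time,
                              interp = c("constant", "linear")) {
  stopifnot(inherits(kin, "cpeptide_kinetics"), inherits(sr, "gutpk_ts"))
  interp <- match.arg(interp)
  if (any(sr$value < 0)) stop("secretion must be >= 0", call. = FALSE)
  M <- cp_matrix(kin)
  if (interp == "constant") {
    knots <- sort(unique(c(sr$time, t_grid)))
    rate_at <- function(t) {
      i <- findInterval(t, sr$time)
      if (i >= 1L && i < length(sr$time)) sr$value[i] else
        if (i == length(sr$time)) 0 else 0
    }
    x <- c(0, 0)
    out <- matrix(NA_real_, nrow = length(knots), ncol = 2L)
    out[1L, ] <- x
    for (k in seq_len(length(knots) - 1L)) {
      s <- rate_at(knots[k])
      x <- cp_step(M, x, s, knots[k + 1L] - knots[k])
      out[k + 1L, ] <- x
    }
    cp1 <- out[match(t_grid, knots), 1L]
  } else {
    sr_fun <- stats::approxfun(sr$time, sr$value, rule = 2)
    rhs <- function(t, y, parms) {
      list(as.numeric(M %*% y) + c(sr_fun(t), 0))
    }
    sol <- deSolve::lsoda(y = c(CP1 = 0, CP2 = 0), times = t_grid,
                          func = rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    cp1 <- sol[, "CP1"]
  }
  timeseries(t_grid, pmax(cp1, 0), "min", "nmol/L")
}

#' Deconvolve the insulin secretion rate from C-peptide data
#'
#' Represents the above-basal secretion `SR(t)` as piecewise constant on
#' the measurement grid extended by one coarse segment to
#' `terminal_basal_time`, where C-peptide is assumed back to basal (the
#' terminal pseudo-observation `CP1 = 0`). The discretized convolution
#' `CP1 = F SR` is solved by penalized least squares with a
#' second-difference (Tikhonov) smoothing term of weight `lambda_reg`, and
#' optionally a non-negativity constraint.
#'
#' `ISR = SR * V1` is reported in pmol/min (with `CP1` in nmol/L and `V1`
#' in mL, `SR * V1` is pmol/min directly), restricted to the measured
#' window, together with its trapezoidal AUC and the model-independent
#' responsivity [phi_responsivity()] when glucose is present in the record.
#'
#' @param record an [ogtt_record()] with a C-peptide series.
#' @param kin a [cpeptide_kinetics()]; defaults to
#'   [kinetics_from_body_weight()] of the record's body weight.
#' @param lambda_reg smoothing weight (dimensionless, relative to the
#'   design scale). `0` requests an unregularized solve, which errors if
#'   the design is singular.
#' @param nonneg enforce `SR >= 0` (active-set solve via bounded BFGS).
#' @param terminal_basal_time time (min) at which C-peptide is assumed
#'   back to basal; default 360.
#' @return an object of class `secretion_profile`: list with `isr` (a step
#'   [timeseries()], pmol/min above basal), `isr_auc` (pmol over the
#'   measured window), `phi`, `sr` (nmol/L/min per segment) and `knots`.
#' @export
deconvolve_isr <- function(record, kin = NULL, lambda_reg = 0.01,
                           nonneg = FALSE, terminal_basal_time = 360) {
  stopifnot(inherits(record, "ogtt_record"))
  if (is.null(record$cpeptide)) stop("record has no C-peptide series",
                                     call. = FALSE)
  if (is.null(kin)) {
    if (!is.finite(record$body_weight)) {
      stop("supply `kin` or a record with body weight", call. = FALSE)
    }
    kin <- kinetics_from_body_weight(record$body_weight)
  }
  cp <- record$cpeptide
  t_meas <- cp$time
  y_meas <- cp$value - cp$basal
  t_end <- t_meas[length(t_meas)]
  if (terminal_basal_time <= t_end) {
    stop("`terminal_basal_time` must exceed the last measurement",
         call. = FALSE)
  }
  knots <- c(t_meas, terminal_basal_time)
  m <- length(knots) - 1L              # number of SR segments
  obs_t <- c(t_meas[-1L], terminal_basal_time)  # CP1(0)=0 carries no info
  obs_y <- c(y_meas[-1L], 0)                    # terminal pinned to basal

  # unit-response design matrix: column j = CP1 at obs_t for SR = 1 on
  # segment j
  M <- cp_matrix(kin)
  F_mat <- matrix(0, nrow = length(obs_t), ncol = m)
  for (j in seq_len(m)) {
    sr_j <- timeseries(knots, c(replace(numeric(m), j, 1), 0), "min",
                       "nmol/L/min")
    resp <- simulate_cpeptide(kin, sr_j, t_grid = sort(unique(c(0, obs_t))),
                              interp = "constant")
    F_mat[, j] <- resp$value[match(obs_t, resp$time)]
  }
  # second-difference penalty, scaled to the design
  if (m >= 3L) {
    D2 <- diff(diag(m), differences = 2L)
  } else D2 <- matrix(0, nrow = 0, ncol = m)
  lam <- lambda_reg * sum(diag(crossprod(F_mat))) /
    max(1, sum(diag(crossprod(D2))))
  H <- crossprod(F_mat) + lam * crossprod(D2)
  g <- crossprod(F_mat, obs_y)
  if (nonneg) {
    obj <- function(s) {
      r <- F_mat %*% s - obs_y
      sum(r^2) + lam * sum((D2 %*% s)^2)
    }
    grad <- function(s) as.numeric(2 * (H %*% s - g))
    s0 <- pmax(qr.solve(H + 1e-10 * diag(m), g), 0)
    opt <- stats::optim(as.numeric(s0), obj, grad, method = "L-BFGS-B",
                        lower = rep(0, m),
                        control = list(maxit = 1000, factr = 1e4))
    sr_hat <- opt$par
  } else {
    sol <- try(solve(H, g), silent = TRUE)
    if (inherits(sol, "try-error")) {
      stop("singular deconvolution design: increase `lambda_reg` or ",
           "provide more samples", call. = FALSE)
    }
    sr_hat <- as.numeric(sol)
  }

  # restrict to the measured window; ISR = SR * V1 (pmol/min)
  seg_len <- diff(knots)
  in_window <- which(knots[-length(knots)] < t_end)
  isr_rates <- sr_hat[in_window] * kin$V1
  isr_step <- timeseries(knots[c(in_window, max(in_window) + 1L)],
                         c(isr_rates, isr_rates[length(isr_rates)]),
                         "min", "pmol/min")
  isr_auc <- sum(isr_rates * seg_len[in_window])
  phi <- if (!is.null(record$glucose)) {
    cp1_ts <- timeseries(t_meas, pmax(y_meas, 0), "min", "nmol/L")
    tryCatch(phi_responsivity(cp1_ts, record$glucose,
                              record$glucose$basal, kin$k01),
             error = function(e) NA_real_)
  } else NA_real_
  structure(list(isr = isr_step, isr_auc = isr_auc, phi = phi,
                 sr = sr_hat, knots = knots, lambda = lam, kin = kin),
            class = "secretion_profile")
}

#' @export
print.secretion_profile <- function(x, ...) {
  cat(sprintf("<secretion profile: ISR AUC = %.4g pmol, phi = %.4g>\n",
              x$isr_auc, x$phi))
  invisible(x)
}

#' Model-independent beta-cell responsivity
#'
#' \deqn{\Phi \approx k_{01} \int CP_1(t) dt \Big/ \int [G(t) - G_b] dt}
#' with both integrals evaluated by the trapezoidal rule over the measured
#' window. Units: (nmol/L C-peptide cleared per min) per (mmol/L min of
#' glucose excursion).
#'
#' @param cp1 a [timeseries()] of above-basal accessible C-peptide (nmol/L).
#' @param glucose a [timeseries()] of glucose (mmol/L).
#' @param Gb basal glucose (mmol/L).
#' @param k01 irreversible C-peptide loss rate (1/min).
#' @return the responsivity ratio (dimensionless nmol/mmol scale).
#' @export
phi_responsivity <- function(cp1, glucose, Gb, k01) {
  stopifnot(inherits(cp1, "gutpk_ts"), inherits(glucose, "gutpk_ts"))
  num <- k01 * ts_trapz(cp1)
  den <- trapz_(glucose$time, glucose$value - Gb)
  if (!is.finite(den) || den <= 0) {
    stop("glucose excursion integral must be positive: phi undefined",
         call. = FALSE)
  }
  num / den
}
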