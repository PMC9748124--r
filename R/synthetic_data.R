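#' Infusion schedule for protein-kinetics experiments
#'
#' Describes the delivery protocol of a recombinant protein: the reference
#' design is a 2-h subcutaneous infusion at 2.5 ng/h followed by washout
#' (`mode = "continuous"`); `"meal"` marks a meal-stimulated native
#' secretion experiment, `"bolus"` a rapid injection.
#'
#' @param rate delivery rate, ng/h (proteins) or pmol/h (antibodies).
#' @param start,stop infusion window, min; `stop > start`.
#' @param mode one of `"continuous"`, `"bolus"`, `"meal"`.
#' @return an object of class `infusion_schedule`.
#' @export
infusion_schedule <- function(rate = 2.5, start = 0, stop = 120,
                              mode = c("continuous", "bolus", "meal")) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, stop > start)
  structure(list(rate = rate, start = start, stop = stop, mode = mode),
            class = "infusion_schedule")
}

#' Generate a noisy serum protein concentration curve
#'
#' Forward-simulates the two-phase Michaelis-Menten model
#' ([simulate_hsp()]) on a fine grid, samples it at `sample_times`, adds
#' the basal level `cb` and applies the measurement-error model of
#' [noise_spec()] (proportional + additive Gaussian, truncated at zero).
#'
#' @param params an [hsp_params()]; its `tmax` should equal the end of the
#'   infusion window of `schedule`.
#' @param schedule an [infusion_schedule()] (documents the protocol; the
#'   inflow shape itself is `A`, `k1`, `k2`, `tmax` of `params`).
#' @param sample_times sampling times, min (default every 5 min to 240).
#' @param noise a [noise_spec()].
#' @return a [timeseries()] of total measured concentration (ng/mL).
#' @export
generate_hsp_series <- function(params, schedule = infusion_schedule(),
                                sample_times = seq(0, 240, by = 5),
                                noise = noise_spec()) {
  stopifnot(inherits(params, "hsp_params"),
            inherits(schedule, "infusion_schedule"))
  sample_times <- as.numeric(sample_times)
  if (any(diff(sample_times) <= 0) || sample_times[1L] < 0) {
    stop("`sample_times` must be strictly increasing, first >= 0",
         call. = FALSE)
  }
  grid <- sort(unique(c(0, sample_times)))
  sim <- simulate_hsp(params, grid)
  c_inc <- sim$value[match(sample_times, grid)]
  total <- apply_noise(c_inc + params$cb, noise)
  timeseries(sample_times, total, "min", "ng/mL", basal = params$cb)
}

#' Generate a noisy antibody fluorescence curve
#'
#' Builds the biphasic subcutaneous inflow from the supplied per-interval
#' AUC fractions (each half of the dose is spread over the sampling
#' intervals before/after `t_peak` proportionally to its fraction),
#' simulates the QSS total-antibody model and returns
#' `RFU(t) = K * At(t)` plus measurement noise.
#'
#' When `inflow_fractions = NULL` (the default) the dose is spread at a
#' uniform rate within each absorption half (fractions proportional to the
#' interval lengths). Note that the AUC-ratio reconstruction used at
#' estimation time ([reconstruct_inflow()]) is an approximation: the
#' concentration AUC lags the inflow that produced it, so the reconstructed
#' profile never reproduces the generating one exactly. Recovery tests
#' should fit against the attached true profile (attribute `"inflow"`).
#'
#' @param params a [tmdd_params()] (its `K` sets the fluorescence scale).
#' @param dose injected dose, pmol.
#' @param inflow_fractions `NULL` for uniform-rate halves, or a list with
#'   elements `first` and `second`: AUC fractions per sampling interval
#'   within each absorption half, each vector summing to 1.
#' @param sample_times sampling times, h, starting at 0 and containing
#'   `t_peak`.
#' @param noise a [noise_spec()].
#' @param t_peak absorption switch time, h (default 2).
#' @return a [timeseries()] of RFU vs h; the generating
#'   [inflow_profile()] is attached as attribute `"inflow"`.
#' @export
generate_mab_rfu_series <- function(params, dose, inflow_fractions = NULL,
                                    sample_times, noise = noise_spec(),
                                    t_peak = 2) {
  stopifnot(inherits(params, "tmdd_params"))
  sample_times <- as.numeric(sample_times)
  if (sample_times[1L] != 0) stop("`sample_times` must start at 0",
                                  call. = FALSE)
  seg_len <- diff(sample_times)
  first_seg <- which(sample_times[-1L] <= t_peak + 1e-9)
  second_seg <- setdiff(seq_along(seg_len), first_seg)

  build_inflow <- function(f1, f2) {
    rates <- numeric(length(seg_len))
    rates[first_seg] <- dose / 2 * f1 / seg_len[first_seg]
    rates[second_seg] <- dose / 2 * f2 / seg_len[second_seg]
    inflow_profile(sample_times, rates)
  }
  if (is.null(inflow_fractions)) {
    f1 <- seg_len[first_seg] / sum(seg_len[first_seg])
    f2 <- seg_len[second_seg] / sum(seg_len[second_seg])
    inflow <- build_inflow(f1, f2)
    sim <- simulate_total_mab(params, inflow, sample_times)
  } else {
    f1 <- inflow_fractions$first
    f2 <- inflow_fractions$second
    if (length(f1) != length(first_seg) || length(f2) != length(second_seg)) {
      stop("fraction vectors must match the sampling intervals per half",
           call. = FALSE)
    }
    for (f in list(f1, f2)) {
      if (length(f) && abs(sum(f) - 1) > 1e-8) {
        stop("inflow fractions must sum to 1 within each half",
             call. = FALSE)
      }
    }
    inflow <- build_inflow(f1, f2)
    sim <- simulate_total_mab(params, inflow, sample_times)
  }
  rfu <- apply_noise(params$K * sim$value, noise)
  structure(timeseries(sample_times, rfu, "h", "RFU"), inflow = inflow)
}

#' Generate a synthetic OGTT record with known ground truth
#'
#' Glucose is simulated from the oral minimal model driven by the supplied
#' insulin curve and, when `glucose_forcing` is given, by the oral
#' appearance term computed from that known reference excursion (the same
#' role the measured glucose plays when the model is fit to real data;
#' keeping the forcing separate makes the generated record exactly
#' consistent with the fitted model, so estimators can be validated by
#' parameter recovery). With no forcing and insulin at basal the record
#' stays at the glucose fixed point `Gb`. C-peptide is simulated from the
#' two-compartment model driven by the true secretion profile. The three
#' series are noised independently (seeds `seed`, `seed+1`, `seed+2`).
#'
#' @param mm an [mm_params()] ground truth.
#' @param cpk a [cpeptide_kinetics()].
#' @param true_isr a [timeseries()] of above-basal ISR (pmol/min), treated
#'   as piecewise constant on its sampling intervals.
#' @param insulin_curve a [timeseries()] of insulin (pmol/L) whose t = 0
#'   value is the basal `Ib`.
#' @param Gb basal glucose, mmol/L.
#' @param Ib basal insulin, pmol/L (defaults to the insulin curve at 0).
#' @param cp_basal basal C-peptide, nmol/L.
#' @param body_weight body weight, g.
#' @param glucose_forcing `NULL` (no oral input) or a [timeseries()] of
#'   the reference glucose excursion (mmol/L) driving the `Ra` term; it is
#'   attached to the result as attribute `"forcing"`.
#' @param sample_times OGTT sampling grid, min.
#' @param noise a [noise_spec()]; its seed governs all three series.
#' @return an [ogtt_record()].
#' @export
generate_ogtt_record <- function(mm, cpk, true_isr, insulin_curve,
                                 Gb = 5.5, Ib = insulin_curve$value[1L],
                                 cp_basal = 0.2, body_weight = 400,
                                 glucose_forcing = NULL,
                                 sample_times = c(0, 20, 40, 60, 80, 100,
                                                  120, 180),
                                 noise = noise_spec()) {
  stopifnot(inherits(mm, "mm_params"), inherits(cpk, "cpeptide_kinetics"),
            inherits(true_isr, "gutpk_ts"),
            inherits(insulin_curve, "gutpk_ts"))
  if (insulin_curve$time[1L] != 0 || true_isr$time[1L] != 0) {
    stop("insulin and ISR curves must start at t = 0 on the OGTT time base",
         call. = FALSE)
  }
  # scaffold record carrying basal levels and the insulin forcing
  scaffold <- ogtt_record(
    glucose = timeseries(sample_times, rep(Gb, length(sample_times)),
                         "min", "mmol/L"),
    insulin = timeseries(sample_times,
                         ts_interp(insulin_curve, sample_times),
                         "min", "pmol/L"),
    body_weight = body_weight
  )
  scaffold$insulin$basal <- Ib
  g_sim <- if (is.null(glucose_forcing)) {
    simulate_minimal_model(mm, scaffold, t_grid = sample_times,
                           ra_mode = "self-consistent")
  } else {
    simulate_minimal_model(mm, scaffold, t_grid = sample_times,
                           ra_mode = "data-driven",
                           forcing_glucose = glucose_forcing)
  }
  sr <- timeseries(true_isr$time, true_isr$value / cpk$V1, "min",
                   "nmol/L/min")
  cp_sim <- simulate_cpeptide(cpk, sr, t_grid = sample_times,
                              interp = "constant")
  noise_g <- noise; noise_g$seed <- noise$seed
  noise_i <- noise; noise_i$seed <- noise$seed + 1L
  noise_c <- noise; noise_c$seed <- noise$seed + 2L
  rec <- ogtt_record(
    glucose = timeseries(sample_times, apply_noise(g_sim$value, noise_g),
                         "min", "mmol/L"),
    insulin = timeseries(sample_times,
                         apply_noise(scaffold$insulin$value, noise_i),
                         "min", "pmol/L"),
    cpeptide = timeseries(sample_times,
                          apply_noise(cp_sim$value + cp_basal, noise_c),
                          "min", "nmol/L"),
    body_weight = body_weight
  )
  attr(rec, "forcing") <- glucose_forcing
  rec
}

#' Generate a synthetic NASH cohort
#'
#' Covariates uniform over the stated ranges; NAS is the model prediction
#' plus Gaussian noise. With `noise_sd = NULL` the noise is calibrated by
#' variance arithmetic so that the population R-squared equals `target_r2`:
#' `sd^2 = var(signal) * (1 - R2)/R2` with
#' `var(signal) = b_h^2 (w_h^2/12) + b_g^2 (w_g^2/12)` for uniform
#' covariates of widths `w`.
#'
#' @param n cohort size (>= 3).
#' @param model a [nas_model()]; default [nas_reference_model()].
#' @param hsp70_range,grp78_range uniform covariate ranges, pg/mL.
#' @param noise_sd Gaussian noise SD on NAS; `NULL` calibrates to
#'   `target_r2`.
#' @param target_r2 population R-squared used when `noise_sd` is `NULL`.
#' @param seed integer seed.
#' @return data frame with columns `hsp70`, `grp78`, `nas`.
#' @export
generate_nash_cohort <- function(n, model = nas_reference_model(),
                                 hsp70_range = c(100, 600),
                                 grp78_range = c(100, 2000),
                                 noise_sd = NULL, target_r2 = 0.78,
                                 seed = 1L) {
  stopifnot(n >= 3)
  if (is.null(noise_sd)) {
    noise_sd <- nash_noise_sd_for_r2(model, hsp70_range, grp78_range,
                                     target_r2)
  }
  with_seed(seed, {
    hsp70 <- stats::runif(n, hsp70_range[1L], hsp70_range[2L])
    grp78 <- stats::runif(n, grp78_range[1L], grp78_range[2L])
    nas <- predict_nas(model, hsp70, grp78) + stats::rnorm(n, 0, noise_sd)
    data.frame(hsp70 = hsp70, grp78 = grp78, nas = nas)
  })
}

#' Noise level giving a target population R-squared for the NAS model
#'
#' @inheritParams generate_nash_cohort
#' @param r2 target population R-squared in (0, 1).
#' @return the Gaussian noise standard deviation.
#' @export
nash_noise_sd_for_r2 <- function(model, hsp70_range, grp78_range, r2) {
  stopifnot(r2 > 0, r2 < 1)
  var_signal <- model$coef_hsp70^2 * diff(hsp70_range)^2 / 12 +
    model$coef_grp78^2 * diff(grp78_range)^2 / 12
  sqrt(var_signal * (1 - r2) / r2)
}
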