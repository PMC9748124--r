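# Canonical synthetic study conditions shared across test files.
# Chosen once to be physiologically plausible and identifiable; the methods
# vignette documents the reasoning.

# Serum chaperone kinetics: 2-h infusion raising serum ~14 ng/mL over a
# 2 ng/mL basal, saturating clearance (Km = 8 ng/mL), fast post-pump
# inflow decay.
hsp_truth <- function() {
  hsp_params(A = 0.4, k1 = 0.05, k2 = 0.1, V = 1, Tm = 0.5, Km = 8,
             cb = 2, tmax = 120)
}
hsp_init <- function() {
  hsp_params(A = 0.5, k1 = 0.04, k2 = 0.13, V = 1, Tm = 0.4, Km = 5,
             cb = 2, tmax = 120)
}
hsp_grid <- function() seq(0, 360, by = 10)

# Anti-HSP mAb: rat-scale volume, elevated circulating target, dose high
# enough that free antibody traverses the KSS region (identifiable fit).
tmdd_truth <- function() {
  tmdd_params(V = 0.044, ke = 0.35, kint = 0.3, KSS = 900, K = 0.8,
              Pbar = 400, D = 200)
}
tmdd_init <- function() {
  tmdd_params(V = 0.04, ke = 0.38, kint = 0.26, KSS = 1080, K = 0.76,
              Pbar = 400, D = 200)
}
tmdd_grid <- function() c(0, 1/3, 2/3, 1, 1.5, 2, 3, 4, 6, 8, 12, 24)

# OGTT: reference glucose excursion (+5 mmol/L peak at 30 min), delayed
# insulin peak, record sampled every 10 min so the fitting grid is exact.
ogtt_forcing <- function() {
  tt <- seq(0, 180, by = 5)
  timeseries(tt, 5.5 + 5.0 * (tt / 30) * exp(1 - tt / 30), "min", "mmol/L")
}
ogtt_insulin <- function() {
  timeseries(c(0, 15, 30, 45, 60, 80, 100, 120, 150, 180),
             c(100, 250, 430, 520, 500, 420, 330, 250, 160, 110),
             "min", "pmol/L")
}
mm_truth <- function() mm_params(SG = 0.02, SI = 1e-4, p = 0.02,
                                 alpha = 0.008, beta = 0.1)
mm_init <- function() mm_params(SG = 0.015, SI = 1.5e-4, p = 0.03,
                                alpha = 0.0065, beta = 0.08)
ogtt_grid <- function() seq(0, 180, by = 10)

# Insulin secretion: square pulse of 60 pmol/min on [20, 60) min over the
# standard OGTT sampling times.
isr_pulse <- function() {
  timeseries(c(0, 20, 40, 60, 80, 100, 120, 180),
             c(0, 60, 60, 0, 0, 0, 0, 0), "min", "pmol/min")
}
rat_cpk <- function() kinetics_from_body_weight(400)

# Disposition-index hyperbola on an SI scale of 1e-4 with points away from
# the asymptotes.
di_truth <- function() list(DI = 500, x_inf = 0.1, y_inf = 2)
di_points <- function(n = 5) {
  si <- seq(0.4, 3.2, length.out = n)
  list(si = si, phi = 500 / (si - 0.1) + 2)
}
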