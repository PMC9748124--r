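#' Measurement-noise specification
#'
#' Combined additive + proportional Gaussian measurement error,
#' `y = value * (1 + eps_prop) + eps_add`, truncated at zero (an ELISA or
#' fluorescence reading cannot be negative). The default proportional CV of
#' 5% is a typical immunoassay intra-assay precision; both components are
#' user-settable.
#'
#' @param additive_sd standard deviation of the additive component, in the
#'   same unit as the signal. Must be >= 0.
#' @param proportional_cv coefficient of variation of the proportional
#'   component (dimensionless fraction in `[0, 1)`).
#' @param seed integer seed; identical seed gives identical noise.
#'
#' @return an object of class `gutpk_noise`.
#' @export
noise_spec <- function(additive_sd = 0, proportional_cv = 0.05, seed = 1L) {
  stopifnot(additive_sd >= 0, proportional_cv >= 0, proportional_cv < 1)
  structure(list(additive_sd = additive_sd,
                 proportional_cv = proportional_cv,
                 seed = as.integer(seed)),
            class = "gutpk_noise")
}

#' Noise-free specification (convenience)
#' @param seed integer seed (irrelevant to output, kept for symmetry).
#' @return a [noise_spec()] with both components zero.
#' @export
noise_off <- function(seed = 1L) noise_spec(0, 0, seed)

# Evaluate `code` under a locally-seeded RNG, restoring the caller's RNG
# state afterwards. All generator randomness flows through this.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Apply the measurement-error model to a vector of true values.
apply_noise <- function(values, noise) {
  stopifnot(inherits(noise, "gutpk_noise"))
  if (noise$additive_sd == 0 && noise$proportional_cv == 0) return(values)
  with_seed(noise$seed, {
    n <- length(values)
    y <- values * (1 + stats::rnorm(n, 0, noise$proportional_cv)) +
      stats::rnorm(n, 0, noise$additive_sd)
    pmax(y, 0)
  })
}
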