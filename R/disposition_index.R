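#' Disposition-index hyperbola
#'
#' The trade-off between beta-cell responsivity and insulin sensitivity
#' across animals of an experiment is summarized by the hyperbola
#' \deqn{y = DI/(x - x_\infty) + y_\infty}
#' where `x` is insulin sensitivity `SI`, `y` is responsivity `Phi`, and
#' `DI` is the product-scale disposition index.
#'
#' @param DI product-scale constant (>= 0 under default bounds).
#' @param x_inf `SI` asymptote.
#' @param y_inf `Phi` asymptote.
#' @return an object of class `di_hyperbola`.
#' @export
di_hyperbola <- function(DI, x_inf = 0, y_inf = 0) {
  stopifnot(is.finite(DI), is.finite(x_inf), is.finite(y_inf))
  structure(list(DI = DI, x_inf = x_inf, y_inf = y_inf),
            class = "di_hyperbola")
}

#' Predict responsivity from insulin sensitivity on the hyperbola
#'
#' @param model a [di_hyperbola()].
#' @param SI insulin sensitivity value(s), must all exceed `x_inf`.
#' @return predicted `Phi` value(s).
#' @export
predict_phi <- function(model, SI) {
  stopifnot(inherits(model, "di_hyperbola"))
  if (any(SI <= model$x_inf)) {
    stop("`SI` must exceed the asymptote x_inf", call. = FALSE)
  }
  model$DI / (SI - model$x_inf) + model$y_inf
}

#' Fit the disposition-index hyperbola to (SI, Phi) pairs
#'
#' Unweighted least squares of `Phi` against `DI/(SI - x_inf) + y_inf`.
#' Default bounds keep the fitted branch physical: `x_inf < min(SI)` and
#' `y_inf < min(Phi)` among the observed points; initialization is
#' `x_inf = y_inf = 0`, `DI = median(SI * Phi)`. Data collinear in
#' `1/SI`-space (fewer than 4 points or a degenerate spread) are flagged,
#' not raised.
#'
#' @param si,phi numeric vectors of per-animal insulin sensitivity and
#'   responsivity (>= 4 points).
#' @param init optional [di_hyperbola()] starting values.
#' @param lower,upper optional named bound overrides over
#'   `(DI, x_inf, y_inf)`.
#' @return a [fit_result()] over `(DI, x_inf, y_inf)`.
#' @export
fit_di <- function(si, phi, init = NULL, lower = NULL, upper = NULL) {
  stopifnot(length(si) == length(phi))
  if (length(si) < 4L) stop("need >= 4 points", call. = FALSE)
  if (is.null(init)) {
    init <- di_hyperbola(DI = stats::median(si * phi), x_inf = 0, y_inf = 0)
  }
  eps_x <- 1e-6 * max(abs(si))
  lo <- c(DI = 0, x_inf = -Inf, y_inf = -Inf)
  hi <- c(DI = Inf, x_inf = min(si) - eps_x, y_inf = min(phi))
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  par0 <- c(DI = init$DI, x_inf = min(init$x_inf, hi[["x_inf"]]),
            y_inf = min(init$y_inf, hi[["y_inf"]]))
  resid_fn <- function(par) {
    par[["DI"]] / (si - par[["x_inf"]]) + par[["y_inf"]] - phi
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lo, upper = hi,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  est <- fit$par
  se <- se_from_nlslm(fit, length(est))
  names(se) <- names(est)
  flags <- character()
  # collinearity in 1/x space: the three-parameter family degenerates when
  # 1/(si - x_inf) has (numerically) no curvature to pin x_inf
  if (stats::sd(si) < 1e-12 * max(abs(si)) ||
      length(unique(signif(si, 12))) < 3L) {
    flags <- "degenerate:collinear"
  }
  fit_result(estimates = est, std_errors = se, residuals = fit$fvec,
             objective = fit$deviance, converged = fit$info %in% 1:3,
             message = fit$message, flags = flags)
}
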