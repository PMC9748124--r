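#' Linear model linking fasting serum chaperones to the NAFLD Activity Score
#'
#' Affine prediction of the histological NAFLD Activity Score (NAS, 0-8)
#' from fasting serum HSP70 and GRP78 concentrations (pg/mL):
#' `NAS = intercept + coef_hsp70 * HSP70 + coef_grp78 * GRP78`.
#'
#' @param intercept intercept, NAS units.
#' @param coef_hsp70 slope per pg/mL HSP70.
#' @param coef_grp78 slope per pg/mL GRP78.
#' @param r2 coefficient of determination of the originating fit (NA when
#'   the model is specified rather than fitted).
#' @param std_coef_hsp70,std_coef_grp78 standardized coefficients.
#' @return an object of class `nas_model`.
#' @export
nas_model <- function(intercept, coef_hsp70, coef_grp78, r2 = NA_real_,
                      std_coef_hsp70 = NA_real_, std_coef_grp78 = NA_real_) {
  structure(list(intercept = intercept, coef_hsp70 = coef_hsp70,
                 coef_grp78 = coef_grp78, r2 = r2,
                 std_coef_hsp70 = std_coef_hsp70,
                 std_coef_grp78 = std_coef_grp78),
            class = "nas_model")
}

#' Reference NAS regression for NASH cohorts
#'
#' The published fasting-serum regression
#' `NAS = -0.368 + 0.009 * HSP70 + 0.002 * GRP78` (concentrations in
#' pg/mL), with reported fit quality R^2 = 0.78 and standardized
#' coefficients 0.581 (HSP70) and 0.438 (GRP78). Under this model a
#' +100 pg/mL change in HSP70 raises predicted NAS by 0.9 points, a
#' +100 pg/mL change in GRP78 by 0.2 points, and both together by 1.1.
#'
#' @return a [nas_model()].
#' @export
nas_reference_model <- function() {
  nas_model(intercept = -0.368, coef_hsp70 = 0.009, coef_grp78 = 0.002,
            r2 = 0.78, std_coef_hsp70 = 0.581, std_coef_grp78 = 0.438)
}

#' Predict NAS from serum HSP70 and GRP78
#'
#' @param model a [nas_model()].
#' @param hsp70,grp78 serum concentrations, pg/mL (vectorized).
#' @return predicted NAS (unbounded affine prediction; the histological
#'   score itself is 0-8).
#' @export
predict_nas <- function(model, hsp70, grp78) {
  stopifnot(inherits(model, "nas_model"), all(hsp70 >= 0), all(grp78 >= 0))
  model$intercept + model$coef_hsp70 * hsp70 + model$coef_grp78 * grp78
}

#' Fit the NAS linear model to a cohort
#'
#' Ordinary least squares of NAS on HSP70 and GRP78, with
#' `r2 = 1 - SSE/SST` and standardized coefficients
#' `coef_j * sd(x_j)/sd(y)` (sample standard deviations, n-1 denominator).
#'
#' @param cohort data frame with columns `hsp70`, `grp78`, `nas`
#'   (concentrations in pg/mL).
#' @return a [nas_model()] with fitted coefficients; the underlying `lm`
#'   fit is attached as attribute `"fit"`.
#' @export
fit_nas <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("hsp70", "grp78", "nas") %in% names(cohort)))
  if (nrow(cohort) < 3L) stop("need >= 3 subjects", call. = FALSE)
  fit <- stats::lm(nas ~ hsp70 + grp78, data = cohort)
  if (anyNA(stats::coef(fit))) {
    stop("singular design: HSP70 and GRP78 are collinear", call. = FALSE)
  }
  cf <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit))$r.squared
  sdy <- stats::sd(cohort$nas)
  out <- nas_model(intercept = unname(cf[1L]),
                   coef_hsp70 = unname(cf["hsp70"]),
                   coef_grp78 = unname(cf["grp78"]),
                   r2 = r2,
                   std_coef_hsp70 = unname(cf["hsp70"]) *
                     stats::sd(cohort$hsp70) / sdy,
                   std_coef_grp78 = unname(cf["grp78"]) *
                     stats::sd(cohort$grp78) / sdy)
  attr(out, "fit") <- fit
  out
}

#' @export
print.nas_model <- function(x, ...) {
  cat(sprintf("NAS = %.4g %+.4g*HSP70 %+.4g*GRP78\n",
              x$intercept, x$coef_hsp70, x$coef_grp78))
  if (!is.na(x$r2)) cat(sprintf("  R^2 = %.3f\n", x$r2))
  if (!is.na(x$std_coef_hsp70)) {
    cat(sprintf("  standardized: HSP70 %.3f, GRP78 %.3f\n",
                x$std_coef_hsp70, x$std_coef_grp78))
  }
  invisible(x)
}
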