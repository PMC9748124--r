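#' Result of a nonlinear least-squares fit
#'
#' Uniform return type of every estimator in the package (`fit_hsp()`,
#' `fit_tmdd()`, `fit_minimal_model()`, `fit_di()`, `fit_nas()` wraps `lm`
#' instead). Non-convergence is reported through the `converged` flag, never
#' as an exception, so batch Monte-Carlo studies can proceed.
#'
#' @param estimates named numeric vector of parameter estimates.
#' @param std_errors named numeric vector of asymptotic standard errors
#'   (NA where not computable).
#' @param residuals residual vector (model minus data) at the optimum.
#' @param objective residual sum of squares at the optimum.
#' @param converged logical convergence flag.
#' @param message optimizer message.
#' @param fixed named list of parameters held fixed during the fit.
#' @param flags character vector of diagnostic flags, e.g.
#'   `"unidentifiable:KSS"`.
#'
#' @return an object of class `gutpk_fit`.
#' @export
fit_result <- function(estimates, std_errors = NULL, residuals = numeric(),
                       objective = NA_real_, converged = NA,
                       message = "", fixed = list(), flags = character()) {
  if (is.null(std_errors)) {
    std_errors <- stats::setNames(rep(NA_real_, length(estimates)),
                                  names(estimates))
  }
  structure(
    list(estimates = estimates, std_errors = std_errors,
         residuals = residuals, objective = objective,
         converged = isTRUE(converged), message = message,
         fixed = fixed, flags = flags),
    class = "gutpk_fit"
  )
}

#' @export
print.gutpk_fit <- function(x, ...) {
  cat("<fit:", if (x$converged) "converged" else "NOT converged",
      sprintf("| RSS = %.6g>\n", x$objective))
  tab <- data.frame(estimate = x$estimates, std_error = x$std_errors)
  print(signif(tab, 6))
  if (length(x$fixed)) {
    cat("fixed:", paste(sprintf("%s = %g", names(x$fixed),
                                unlist(x$fixed)), collapse = ", "), "\n")
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.gutpk_fit <- function(object, ...) object$estimates

# Standard errors from a minpack.lm::nls.lm fit (same convention as
# summary.nls.lm); NAs when the information matrix is singular.
se_from_nlslm <- function(fit, n_par) {
  ih <- try(chol2inv(chol(fit$hessian)), silent = TRUE)
  rdf <- max(1L, length(fit$fvec) - n_par)
  if (inherits(ih, "try-error") || any(!is.finite(diag(ih)))) {
    return(rep(NA_real_, n_par))
  }
  sqrt(pmax(0, diag(ih)) * fit$deviance / rdf)
}
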