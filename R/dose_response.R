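#' Construct a single-agent dose-response curve
#'
#' @param drug Drug identifier.
#' @param cell_line Cell-line identifier.
#' @param concentrations Doses in uM, all > 0.
#' @param viabilities Normalized viability fractions (>= 0), same length.
#' @return A `dose_response_curve` object.
#' @export
dose_response_curve <- function(drug, cell_line, concentrations, viabilities) {
  if (length(concentrations) != length(viabilities)) {
    stop("concentrations and viabilities must have equal length")
  }
  if (length(concentrations) < 4) stop("a dose-response curve needs >= 4 points")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be finite and > 0")
  }
  if (any(!is.finite(viabilities)) || any(viabilities < 0)) {
    stop("viabilities must be finite and >= 0")
  }
  ord <- order(concentrations)
  structure(
    list(drug = drug, cell_line = cell_line,
         concentrations = concentrations[ord], viabilities = viabilities[ord],
         max_conc = max(concentrations)),
    class = "dose_response_curve"
  )
}

#' Hill-equation viability
#'
#' Four-parameter logistic response:
#' `v(c) = e_inf + (e0 - e_inf) / (1 + (c / ic50)^h)`.
#' At `c = ic50` the response is the midpoint `(e0 + e_inf) / 2`; at `c = 0`
#' it is `e0`.
#'
#' @param conc Concentration(s), uM (>= 0).
#' @param ic50 Midpoint concentration, uM.
#' @param hill_slope Hill coefficient (> 0).
#' @param e0 Zero-dose asymptote (viability scale).
#' @param e_inf Infinite-dose asymptote.
#' @return Viability fraction(s).
#' @export
hill_viability <- function(conc, ic50, hill_slope = 1, e0 = 1, e_inf = 0) {
  if (any(conc < 0)) stop("conc must be >= 0")
  e_inf + (e0 - e_inf) / (1 + (conc / ic50)^hill_slope)
}

#' Invert a Hill fit at a target inhibition level
#'
#' Returns the dose producing `effect_level` inhibition of normalized
#' viability (i.e. viability `1 - effect_level`, inhibition measured against
#' the no-drug control). `Inf` when the fitted curve never reaches that
#' viability; `0` when it already sits at or below it with no drug.
#'
#' @param fit A `hill_fit` from [fit_hill()] (the uncensored parameters are
#'   used; censoring handling is the caller's responsibility).
#' @param effect_level Inhibition fraction in (0, 1).
#' @return Dose in uM.
#' @export
hill_inverse <- function(fit, effect_level) {
  if (effect_level <= 0 || effect_level >= 1) {
    stop("effect_level must be in (0, 1)")
  }
  v <- 1 - effect_level
  if (v <= fit$e_inf) return(Inf)
  if (v >= fit$e0) return(0)
  r <- (fit$e0 - v) / (v - fit$e_inf)
  fit$ic50_fitted * r^(1 / fit$hill_slope)
}

#' Default Hill-fit options
#'
#' @param max_iter Maximum optimizer iterations per start.
#' @param tol Convergence tolerance on the mean-squared-error objective.
#' @param e0_bounds,e_inf_bounds Bounds for the asymptotes.
#' @param slope_bounds Bounds for the Hill coefficient.
#' @param seed Integer seed (fitting is deterministic; the seed is recorded
#'   for provenance).
#' @return List of fitting options.
#' @export
hill_fit_options <- function(max_iter = 5000, tol = 1e-8,
                             e0_bounds = c(0.5, 1.5),
                             e_inf_bounds = c(0, 1.2),
                             slope_bounds = c(0.1, 10),
                             seed = 1L) {
  list(max_iter = max_iter, tol = tol, e0_bounds = e0_bounds,
       e_inf_bounds = e_inf_bounds, slope_bounds = slope_bounds, seed = seed)
}

#' Fit the Hill equation to a dose-response curve
#'
#' Least-squares fit of the 4-parameter Hill model on the log10-dose scale,
#' using bounded gradient-based optimization (L-BFGS-B) from a deterministic
#' multi-start grid of initial midpoints and slopes. If the fitted curve
#' never reaches 50% inhibition of normalized viability (relative to the
#' no-drug control, viability 1) anywhere in the tested dose range, the IC50
#' is censored at the bound `max_conc` and reported as the inequality
#' IC50 >= max_conc.
#'
#' @param curve A [dose_response_curve()].
#' @param opts Options from [hill_fit_options()].
#' @return A `hill_fit` object with fields `ic50` (bound when censored),
#'   `ic50_fitted` (unconstrained optimum), `hill_slope`, `e0`, `e_inf`,
#'   `censored`, `max_conc`, `loss` (mean squared error), `converged`.
#' @export
fit_hill <- function(curve, opts = hill_fit_options()) {
  if (!inherits(curve, "dose_response_curve")) {
    stop("curve must be a dose_response_curve")
  }
  conc <- curve$concentrations
  y <- curve$viabilities
  lc <- log10(conc)

  # parameters: log10(ic50), log(slope), e0, e_inf
  obj <- function(theta) {
    v <- hill_viability(conc, 10^theta[1], exp(theta[2]), theta[3], theta[4])
    mean((v - y)^2)
  }
  lower <- c(min(lc) - 3, log(opts$slope_bounds[1]),
             opts$e0_bounds[1], opts$e_inf_bounds[1])
  upper <- c(max(lc) + 3, log(opts$slope_bounds[2]),
             opts$e0_bounds[2], opts$e_inf_bounds[2])

  e_inf0 <- min(max(min(y), opts$e_inf_bounds[1]), opts$e_inf_bounds[2])
  starts <- expand.grid(
    lic50 = stats::quantile(lc, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE),
    lslope = log(c(0.5, 1, 2))
  )
  best <- NULL
  best_conv <- NULL
  for (i in seq_len(nrow(starts))) {
    theta0 <- c(starts$lic50[i], starts$lslope[i], 1, e_inf0)
    res <- tryCatch(
      stats::optim(theta0, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = opts$max_iter,
                                  factr = opts$tol / .Machine$double.eps)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0 &&
        (is.null(best_conv) || res$value < best_conv$value)) best_conv <- res
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  # prefer a formally converged start whose objective ties the overall best
  if (!is.null(best_conv) && best_conv$value - best$value <= opts$tol) {
    best <- best_conv
  }
  # an essentially-zero objective is a perfect fit even when the line search
  # aborts on a flat error surface
  converged <- best$convergence == 0 || best$value < opts$tol
  if (!converged) warning("Hill fit did not formally converge; returning best iterate")

  theta <- best$par
  ic50_fitted <- 10^theta[1]
  slope <- exp(theta[2])
  e0 <- theta[3]
  e_inf <- theta[4]

  # censoring rule: fitted inhibition (relative to control = 1) must reach
  # 50% somewhere within [min dose, max_conc]
  grid <- 10^seq(min(lc), max(lc), length.out = 256)
  vmin <- min(hill_viability(grid, ic50_fitted, slope, e0, e_inf))
  censored <- vmin > 0.5

  structure(
    list(ic50 = if (censored) curve$max_conc else ic50_fitted,
         ic50_fitted = ic50_fitted, hill_slope = slope, e0 = e0,
         e_inf = e_inf, censored = censored, max_conc = curve$max_conc,
         loss = best$value, converged = converged,
         drug = curve$drug, cell_line = curve$cell_line),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  ic <- if (x$censored) sprintf("IC50 >= %.4g uM (censored)", x$max_conc)
        else sprintf("IC50 = %.4g uM", x$ic50)
  cat(sprintf("<hill_fit> %s: %s, slope %.3g, e0 %.3g, e_inf %.3g, mse %.3g\n",
              if (is.null(x$drug)) "" else x$drug, ic, x$hill_slope,
              x$e0, x$e_inf, x$loss))
  invisible(x)
}

#' Normalized area under the dose-response curve
#'
#' Trapezoidal integral of viability over log10 concentration, divided by
#' the log10 dose span, so a flat no-effect curve (viability 1 everywhere)
#' scores exactly 1 and complete kill scores 0.
#'
#' @param curve A [dose_response_curve()] (or any object with positive
#'   `concentrations` and `viabilities`).
#' @return List with `auc` and `normalized = TRUE`.
#' @export
compute_auc <- function(curve) {
  conc <- curve$concentrations
  v <- curve$viabilities
  if (length(conc) < 2) stop("AUC requires at least 2 points")
  ord <- order(conc)
  lc <- log10(conc[ord])
  span <- max(lc) - min(lc)
  if (span <= 0) stop("AUC requires a nonzero dose span")
  list(auc = pracma::trapz(lc, v[ord]) / span, normalized = TRUE)
}
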