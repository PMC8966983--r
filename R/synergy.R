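#' Chou-Talalay Combination Index at one dose pair
#'
#' `CI = C_A / IC_xx_A + C_B / IC_xx_B`, where `(C_A, C_B)` is a combination
#' dose pair achieving `effect_level` inhibition and `IC_xx` is the
#' single-agent dose for that same effect, inverted from each drug's Hill
#' fit. CI < 1 indicates synergy, 1 additivity, > 1 antagonism.
#'
#' When a single agent never reached 50% inhibition its IC50 is only known
#' as the inequality IC50 >= max_conc; the bound `max_conc` is then
#' substituted for the IC_xx, the resulting CI is flagged as a lower bound
#' (`ci_is_lower_bound`), and its status is `"censored_bound"`.
#'
#' @param conc_a,conc_b Combination doses (uM) achieving the effect.
#' @param fit_a,fit_b `hill_fit` objects for the two single agents.
#' @param effect_level Inhibition fraction in (0, 1).
#' @return One-row data.frame: `effect_level`, `conc_a`, `conc_b`,
#'   `ic_xx_a`, `ic_xx_b`, `ci`, `ci_is_lower_bound`, `status`.
#' @export
compute_ci <- function(conc_a, conc_b, fit_a, fit_b, effect_level) {
  if (effect_level <= 0 || effect_level >= 1) {
    stop("effect_level must be in (0, 1)")
  }
  ic_a <- if (fit_a$censored) fit_a$max_conc else hill_inverse(fit_a, effect_level)
  ic_b <- if (fit_b$censored) fit_b$max_conc else hill_inverse(fit_b, effect_level)
  term <- function(conc, ic) if (conc == 0) 0 else conc / ic
  ci <- term(conc_a, ic_a) + term(conc_b, ic_b)
  bound <- (fit_a$censored && conc_a > 0) || (fit_b$censored && conc_b > 0)
  data.frame(
    effect_level = effect_level, conc_a = conc_a, conc_b = conc_b,
    ic_xx_a = ic_a, ic_xx_b = ic_b, ci = ci,
    ci_is_lower_bound = bound,
    status = if (bound) "censored_bound" else "computed",
    stringsAsFactors = FALSE
  )
}

#' Combination indices over the iso-effect contours of a GP surface
#'
#' For each requested effect level, extracts the iso-effect contour from the
#' fitted surface ([find_isoeffect()]) and evaluates the Combination Index
#' at every contour point. Levels the surface never reaches within the
#' measured dose range yield a single `not_reached` record with no CI value,
#' honoring the rule that no CI is calculated when the desired effect is not
#' reached in the combination screen.
#'
#' @param surface A `gp_surface` from [fit_gp_surface()].
#' @param fit_a,fit_b Single-agent `hill_fit` objects.
#' @param effect_levels Inhibition fractions (default 0.25, 0.5, 0.75).
#' @param n_rays,tol Contour-tracing controls, see [find_isoeffect()].
#' @return data.frame of CI records (one row per contour point, plus one
#'   `not_reached` row per unreached level).
#' @export
ci_over_grid <- function(surface, fit_a, fit_b,
                         effect_levels = c(0.25, 0.5, 0.75),
                         n_rays = 50, tol = 1e-3) {
  out <- lapply(effect_levels, function(lev) {
    contour <- find_isoeffect(surface, lev, n_rays = n_rays, tol = tol)
    if (!contour$reached) {
      return(data.frame(
        effect_level = lev, conc_a = NA_real_, conc_b = NA_real_,
        ic_xx_a = NA_real_, ic_xx_b = NA_real_, ci = NA_real_,
        ci_is_lower_bound = FALSE, status = "not_reached",
        stringsAsFactors = FALSE
      ))
    }
    do.call(rbind, lapply(seq_len(nrow(contour$points)), function(i) {
      compute_ci(contour$points$conc_a[i], contour$points$conc_b[i],
                 fit_a, fit_b, lev)
    }))
  })
  do.call(rbind, out)
}

#' Identify the minimum-CI (maximal-synergy) dosing regimen
#'
#' The optimal regimen is the dose pair with the smallest fully computed CI
#' across the searched effect levels and contour points. CI values that are
#' only lower bounds (censored single agents) are excluded, since their true
#' CI is unknown; ties on CI are broken by the smallest total concentration.
#'
#' @param results CI records from [ci_over_grid()] (or rbind of
#'   [compute_ci()] rows).
#' @return List with `conc_a`, `conc_b`, `min_ci`, `effect_level`.
#' @export
min_ci_regimen <- function(results) {
  ok <- results[results$status == "computed" & is.finite(results$ci), ,
                drop = FALSE]
  if (nrow(ok) == 0) {
    stop(structure(
      class = c("synerscreen_no_regimen", "error", "condition"),
      list(message = "no computed CI values; optimal regimen is undefined",
           call = sys.call(-1))
    ))
  }
  ok$total <- ok$conc_a + ok$conc_b
  ok <- ok[order(ok$ci, ok$total), , drop = FALSE]
  list(conc_a = ok$conc_a[1], conc_b = ok$conc_b[1],
       min_ci = ok$ci[1], effect_level = ok$effect_level[1])
}

#' Bliss beta synergy coefficient for a combination grid
#'
#' For every interior cell (both doses nonzero) the Bliss-expected
#' inhibition is `e_ij = 1 - (1 - a_i)(1 - b_j)`, where `a_i`, `b_j` are the
#' single-agent inhibitions read from the grid's zero-dose margins. Beta is
#' the least-squares slope through the origin of observed inhibition against
#' Bliss-expected inhibition over all interior cells with positive expected
#' inhibition: beta = 1 is Bliss-additive, > 1 synergistic, < 1
#' antagonistic.
#'
#' @param grid A [combination_grid()] with embedded zero-dose margins.
#' @return List with `beta` and `n_cells` (interior cells used).
#' @export
compute_bliss_beta <- function(grid) {
  if (!inherits(grid, "combination_grid")) stop("grid must be a combination_grid")
  ia <- which(grid$doses_a == 0)
  ib <- which(grid$doses_b == 0)
  if (length(ia) != 1 || length(ib) != 1) {
    stop("grid must embed single-agent margins (one zero dose per axis)")
  }
  a <- 1 - grid$viabilities[, ib]   # margin inhibition of drug A at each dose
  b <- 1 - grid$viabilities[ia, ]
  rows <- setdiff(seq_along(grid$doses_a), ia)
  cols <- setdiff(seq_along(grid$doses_b), ib)
  expected <- 1 - outer(1 - a[rows], 1 - b[cols])
  observed <- 1 - grid$viabilities[rows, cols, drop = FALSE]
  use <- expected > 0
  if (!any(use)) stop("all Bliss-expected inhibitions are zero; beta undefined")
  e <- expected[use]; o <- observed[use]
  list(beta = sum(o * e) / sum(e * e), n_cells = sum(use))
}

#' Spearman concordance between Bliss beta and minimum CI
#'
#' Rank correlation of the two synergy scores over paired drug-pair x
#' cell-line combinations (average ranks for ties). Synergy raises beta and
#' lowers CI, so concordant metrics give a negative rho.
#'
#' @param betas Numeric vector of Bliss beta values.
#' @param cis Numeric vector of minimum CI values, paired with `betas`.
#' @return Spearman's rho.
#' @export
correlate_synergy_metrics <- function(betas, cis) {
  if (length(betas) != length(cis)) {
    stop("betas and cis must be paired (equal length)")
  }
  if (length(betas) < 3) stop("need at least 3 pairs")
  stats::cor(betas, cis, method = "spearman")
}
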