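fit_from_params <- function(ic50, slope = 1, top = 10) {
  fit_hill(make_hill_curve(ic50, slope = slope, top = top))
}

test_that("the combination index follows the two-term formula", {
  fa <- fit_from_params(0.2)
  fb <- fit_from_params(0.8)
  r <- compute_ci(0.2 / 2, 0.8 / 2, fa, fb, 0.5)
  expect_equal(r$ci, 1, tolerance = 1e-3)
  expect_equal(r$status, "computed")
  expect_false(r$ci_is_lower_bound)

  r2 <- compute_ci(0.2 / 4, 0.8 / 4, fa, fb, 0.5)
  expect_equal(r2$ci, 0.5, tolerance = 1e-3)
})

test_that("censored single agents propagate as CI lower bounds", {
  s <- build_single_agent_series("b", 1, 13, 3)
  flat <- fit_hill(dose_response_curve("b", "l", s$concentrations, rep(1, 13)))
  expect_true(flat$censored)
  fa <- fit_from_params(0.2)
  r <- compute_ci(0, 0.5, fa, flat, 0.5)
  expect_equal(r$ci, 0.5)
  expect_true(r$ci_is_lower_bound)
  expect_equal(r$status, "censored_bound")
  expect_equal(r$ic_xx_b, 1)  # the bound max_conc stands in for IC50
})

test_that("CI scales linearly with the combination doses", {
  fa <- fit_from_params(0.15, slope = 1.3)
  fb <- fit_from_params(0.6, slope = 0.7)
  base <- compute_ci(0.05, 0.2, fa, fb, 0.5)$ci
  for (lam in c(0.25, 0.5, 2, 7.5)) {
    expect_equal(compute_ci(lam * 0.05, lam * 0.2, fa, fb, 0.5)$ci,
                 lam * base)
  }
})

test_that("noise-free Loewe sham self-combinations give CI = 1 on all contours", {
  p <- list(ic50 = 0.1, slope = 1, e0 = 1, e_inf = 0)
  spec <- generator_spec(seed = 1, noise_sd = 0, hill_a = p, hill_b = p,
                         surface_mode = "loewe")
  ax <- build_combination_axis(0.3)
  g <- gen_combination_grid(spec, ax, ax, "A", "A")
  surf <- fit_gp_surface(g$grid)
  s13 <- build_single_agent_series("A", 0.3, 13, 3)
  fit <- fit_hill(dose_response_curve(
    "A", "l", s13$concentrations,
    hill_viability(s13$concentrations, 0.1)
  ))
  res <- ci_over_grid(surf, fit, fit, c(0.25, 0.5, 0.75))
  expect_true(all(res$status == "computed"))
  expect_lt(max(abs(res$ci - 1)), 0.05)
})

test_that("no CI is calculated when the surface never reaches the effect", {
  spec <- generator_spec(seed = 1, noise_sd = 0,
                         hill_a = list(ic50 = 10, slope = 1, e0 = 1, e_inf = 0),
                         hill_b = list(ic50 = 50, slope = 1, e0 = 1, e_inf = 0))
  g <- gen_combination_grid(spec, build_combination_axis(0.9),
                            build_combination_axis(4.5))
  surf <- fit_gp_surface(g$grid)
  fa <- fit_from_params(0.1, top = 0.9)
  fb <- fit_from_params(0.5, top = 4.5)
  res <- ci_over_grid(surf, fa, fb, 0.5)
  expect_true(all(res$status == "not_reached"))
  expect_true(all(is.na(res$ci)))
})

test_that("a Bliss-generated surface shows synergy relative to Loewe on the 50% contour", {
  spec <- generator_spec(seed = 1, noise_sd = 0,
                         hill_a = list(ic50 = 0.1, slope = 1, e0 = 1, e_inf = 0),
                         hill_b = list(ic50 = 0.5, slope = 1, e0 = 1, e_inf = 0),
                         surface_mode = "bliss")
  g <- gen_combination_grid(spec, build_combination_axis(0.9),
                            build_combination_axis(4.5))
  surf <- fit_gp_surface(g$grid)
  fa <- fit_from_params(0.1, top = 0.9)
  fb <- fit_from_params(0.5, top = 4.5)
  res <- ci_over_grid(surf, fa, fb, 0.5)
  expect_true(any(res$ci < 1, na.rm = TRUE))
})

test_that("the minimum-CI regimen takes the smallest computed CI with ties by total dose", {
  res <- data.frame(
    effect_level = 0.5,
    conc_a = c(0.01, 0.1, 1, 0.01),
    conc_b = c(0.1, 1, 0.1, 0.5),
    ic_xx_a = 1, ic_xx_b = 1,
    ci = c(0.4, 0.6, 0.6, 0.35),
    ci_is_lower_bound = c(FALSE, FALSE, FALSE, TRUE),
    status = c("computed", "computed", "computed", "censored_bound"),
    stringsAsFactors = FALSE
  )
  best <- min_ci_regimen(res)
  expect_equal(best$min_ci, 0.4)            # censored bound 0.35 excluded
  expect_equal(c(best$conc_a, best$conc_b), c(0.01, 0.1))

  tie <- res[2:3, ]
  tie$status <- "computed"
  best_tie <- min_ci_regimen(tie)
  expect_equal(best_tie$conc_a + best_tie$conc_b, 1.1)

  nr <- res
  nr$status <- "not_reached"
  nr$ci <- NA_real_
  expect_error(min_ci_regimen(nr), class = "synerscreen_no_regimen")
})

test_that("Bliss beta is 1 on exact-Bliss grids and scales with inhibition", {
  da <- build_combination_axis(0.9)
  db <- build_combination_axis(4.5)
  va <- hill_viability(da, 0.1)
  vb <- hill_viability(db, 0.5)
  exact <- combination_grid("A", "B", da, db, outer(va, vb))
  expect_equal(compute_bliss_beta(exact)$beta, 1, tolerance = 1e-9)
  expect_equal(compute_bliss_beta(exact)$n_cells, 36)

  # observed inhibition exactly half the Bliss expectation -> beta 0.5
  inh <- 1 - outer(va, vb)
  half <- 1 - 0.5 * inh
  half[1, ] <- vb  # keep the single-agent margins intact
  half[, 1] <- va
  g_half <- combination_grid("A", "B", da, db, half)
  expect_equal(compute_bliss_beta(g_half)$beta, 0.5, tolerance = 1e-9)

  # proportional synergy below the cap -> beta equals the multiplier
  spec <- generator_spec(seed = 1, noise_sd = 0,
                         hill_a = list(ic50 = 2.7, slope = 1, e0 = 1, e_inf = 0),
                         hill_b = list(ic50 = 13.5, slope = 1, e0 = 1, e_inf = 0),
                         surface_mode = "synergy", synergy_strength = 0.5)
  g <- gen_combination_grid(spec, da, db)
  expect_equal(compute_bliss_beta(g$grid)$beta, 1.5, tolerance = 1e-9)
})

test_that("Bliss beta is invariant to transposing the grid", {
  spec <- generator_spec(seed = 3, noise_sd = 0.05)
  g <- gen_combination_grid(spec)$grid
  flipped <- combination_grid(g$drug_b, g$drug_a, g$doses_b, g$doses_a,
                              t(g$viabilities))
  expect_equal(compute_bliss_beta(flipped)$beta, compute_bliss_beta(g)$beta)
})

test_that("Bliss beta stays calibrated under noise and detects planted synergy", {
  betas <- vapply(1:25, function(s) {
    g <- gen_combination_grid(generator_spec(seed = s, noise_sd = 0.05))
    compute_bliss_beta(g$grid)$beta
  }, numeric(1))
  expect_gt(mean(betas), 0.9)
  expect_lt(mean(betas), 1.1)

  syn <- vapply(1:25, function(s) {
    spec <- generator_spec(seed = s, noise_sd = 0.05,
                           surface_mode = "synergy", synergy_strength = 0.3)
    compute_bliss_beta(gen_combination_grid(spec)$grid)$beta
  }, numeric(1))
  expect_gte(mean(syn > 1), 0.9)
})

test_that("Spearman concordance matches the rank-correlation oracle", {
  expect_equal(correlate_synergy_metrics(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(correlate_synergy_metrics(c(1, 2, 3), c(1, 2, 3)), 1)
  b <- c(1, 2, 3, 4); ci <- c(2, 1, 4, 3)
  expect_equal(correlate_synergy_metrics(b, ci), spearman_oracle(b, ci))
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(correlate_synergy_metrics(x, y), spearman_oracle(x, y))
  }
  expect_error(correlate_synergy_metrics(1:3, 1:4), "paired")
  expect_error(correlate_synergy_metrics(1:2, 2:1), "at least 3")
})
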