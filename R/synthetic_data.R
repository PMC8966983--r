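#' Specification for the synthetic-data generators
#'
#' Bundles the seed and the ground-truth parameters used by every
#' generator. Defaults emulate the screening design analyzed by the
#' package: 13-point three-fold single-agent series, 7x7 combination
#' matrices with a zero-dose margin, drug-vs-vehicle RPPA with two
#' timepoints and two sensitivity classes at three samples per arm, and
#' exponential xenograft growth with a group-level treatment effect.
#'
#' @param seed Integer seed; fully determines every generated dataset
#'   (R's default Mersenne-Twister RNG).
#' @param noise_sd Additive Gaussian noise SD on the viability scale
#'   (truncated at 0), default 0.05.
#' @param hill_a,hill_b Ground-truth Hill parameters for the two drugs:
#'   lists with `ic50` (uM), `slope`, `e0`, `e_inf`.
#' @param surface_mode How combination surfaces are generated: `"bliss"`
#'   (exact Bliss independence), `"loewe"` (exact Loewe additivity by
#'   bisection), or `"synergy"` (Bliss inhibition scaled by
#'   `1 + synergy_strength`, capped at 1; negative strength gives
#'   antagonism).
#' @param synergy_strength Unitless s >= -1 used by `"synergy"` mode.
#' @param rppa_spec List: `n_antibodies`, `n_planted`, `effect_size`
#'   (log2), `noise_sd`, `n_per_arm`, `planted_timepoints`,
#'   `planted_classes`.
#' @param growth_spec List: `baseline_volume` (mm^3), `growth_rate`
#'   (per day), `treatment_multiplier`, `treatment_start_day`,
#'   `growth_rate_sd` (between-animal), `measurement_noise_sd`
#'   (log-scale multiplicative).
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(seed = 1L,
                           noise_sd = 0.05,
                           hill_a = list(ic50 = 0.1, slope = 1, e0 = 1, e_inf = 0),
                           hill_b = list(ic50 = 0.5, slope = 1, e0 = 1, e_inf = 0),
                           surface_mode = c("bliss", "loewe", "synergy"),
                           synergy_strength = 0,
                           rppa_spec = list(),
                           growth_spec = list()) {
  surface_mode <- match.arg(surface_mode)
  if (synergy_strength < -1) stop("synergy_strength must be >= -1")
  rppa_default <- list(n_antibodies = 1000L, n_planted = 50L, effect_size = 1,
                       noise_sd = 0.25, n_per_arm = 3L,
                       planted_timepoints = c("24h", "72h"),
                       planted_classes = c("sensitive", "resistant"))
  growth_default <- list(baseline_volume = 350, growth_rate = 0.05,
                         treatment_multiplier = 0.28, treatment_start_day = 0,
                         growth_rate_sd = 0.005, measurement_noise_sd = 0.05)
  rppa <- utils::modifyList(rppa_default, rppa_spec)
  growth <- utils::modifyList(growth_default, growth_spec)
  if (rppa$n_planted > rppa$n_antibodies) {
    stop("n_planted cannot exceed n_antibodies")
  }
  structure(
    list(seed = as.integer(seed), noise_sd = noise_sd,
         hill_a = hill_a, hill_b = hill_b,
         surface_mode = surface_mode, synergy_strength = synergy_strength,
         rppa_spec = rppa, growth_spec = growth),
    class = "generator_spec"
  )
}

hill_eval <- function(params, conc) {
  hill_viability(conc, params$ic50, params$slope, params$e0, params$e_inf)
}

#' Generate a single-agent viability plate with known truth
#'
#' Viabilities follow the ground-truth Hill model at the series doses, with
#' additive Gaussian noise (truncated at 0), and are converted to raw
#' absorbance signals against no-drug control wells on the same plate.
#'
#' @param spec A [generator_spec()].
#' @param series A [build_single_agent_series()] dose series.
#' @param cell_line Cell-line identifier attached to the truth record.
#' @param n_controls Number of no-drug control wells (default 8).
#' @param control_scale Raw absorbance of an untreated well (arbitrary
#'   units, default 1.5).
#' @return List with `wells` (plate table as from [read_plate()]) and
#'   `truth` (the Hill parameters and series used).
#' @export
gen_single_agent_plate <- function(spec, series, cell_line = "line1",
                                   n_controls = 8, control_scale = 1.5) {
  set.seed(spec$seed)
  conc <- series$concentrations
  viab <- hill_eval(spec$hill_a, conc)
  noisy <- pmax(0, viab + stats::rnorm(length(conc), 0, spec$noise_sd))
  ctrl <- pmax(0, 1 + stats::rnorm(n_controls, 0, spec$noise_sd))
  n <- length(conc) + n_controls
  wells <- data.frame(
    plate_id = "synthetic1",
    well = paste0("A", seq_len(n)),
    row = "A", col = seq_len(n),
    drug_a = c(rep(series$drug, length(conc)), rep(NA_character_, n_controls)),
    conc_a = c(conc, rep(0, n_controls)),
    drug_b = NA_character_, conc_b = 0,
    raw_signal = control_scale * c(noisy, ctrl),
    stringsAsFactors = FALSE
  )
  wells$is_control <- wells$conc_a == 0 & wells$conc_b == 0
  list(wells = wells,
       truth = list(cell_line = cell_line, hill = spec$hill_a,
                    series = series, noise_sd = spec$noise_sd))
}

# dose of one drug alone producing inhibition E (relative to viability 1)
dose_for_effect <- function(params, E) {
  v <- 1 - E
  if (v <= params$e_inf) return(Inf)
  if (v >= params$e0) return(0)
  params$ic50 * ((params$e0 - v) / (v - params$e_inf))^(1 / params$slope)
}

# Loewe-additive effect at a dose pair: solve dA/DA(E) + dB/DB(E) = 1
loewe_effect <- function(da, db, pa, pb, tol = 1e-8, max_iter = 200) {
  if (da == 0 && db == 0) return(0)
  if (da == 0) return(1 - hill_eval(pb, db))
  if (db == 0) return(1 - hill_eval(pa, da))
  hi <- min(1 - pa$e_inf, 1 - pb$e_inf) - 1e-12
  lo <- 1e-12
  f <- function(E) da / dose_for_effect(pa, E) + db / dose_for_effect(pb, E) - 1
  if (f(hi) > 0) return(hi)   # doses exceed the whole measurable range
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) return((lo + hi) / 2)
  }
  stop("Loewe bisection did not converge")
}

#' Generate a combination dose-response grid with known truth
#'
#' Single-agent margins come from the ground-truth Hill models; interior
#' cells follow the configured null/synergy model: exact Bliss independence
#' (`viability = vA * vB`), exact Loewe additivity (effect solved per cell
#' by bisection), or Bliss inhibition scaled by `1 + synergy_strength`
#' (capped at 1). Gaussian noise is added last and the matrix renormalized
#' so the double-zero cell is exactly 1, mirroring control normalization.
#'
#' @param spec A [generator_spec()].
#' @param doses_a,doses_b Dose axes in uM, increasing, including a zero
#'   dose (defaults: the 0.03 uM and 1 uM three-fold combination axes).
#' @param drug_a,drug_b Axis drug identifiers.
#' @return List with `grid` (a [combination_grid()]) and `truth` (mode,
#'   strength, Hill parameters, and the noise-free viability matrix).
#' @export
gen_combination_grid <- function(spec,
                                 doses_a = build_combination_axis(0.03),
                                 doses_b = build_combination_axis(1),
                                 drug_a = "drugA", drug_b = "drugB") {
  set.seed(spec$seed)
  pa <- spec$hill_a; pb <- spec$hill_b
  va <- hill_eval(pa, doses_a)
  vb <- hill_eval(pb, doses_b)
  v <- switch(spec$surface_mode,
    bliss = outer(va, vb),
    loewe = {
      m <- matrix(0, length(doses_a), length(doses_b))
      for (i in seq_along(doses_a)) {
        for (j in seq_along(doses_b)) {
          m[i, j] <- 1 - loewe_effect(doses_a[i], doses_b[j], pa, pb)
        }
      }
      m
    },
    synergy = {
      # single-agent margins stay at their Hill response; only true
      # combination cells (both doses nonzero) get the synergy multiplier
      inh <- 1 - outer(va, vb)
      interior <- outer(doses_a > 0, doses_b > 0, "&")
      inh[interior] <- pmin(1, (1 + spec$synergy_strength) * inh[interior])
      1 - inh
    }
  )
  v_true <- v
  if (spec$noise_sd > 0) {
    v <- pmax(v + matrix(stats::rnorm(length(v), 0, spec$noise_sd),
                         nrow(v), ncol(v)), 0)
    v <- v / v[doses_a == 0, doses_b == 0]
  }
  list(grid = combination_grid(drug_a, drug_b, doses_a, doses_b, v),
       truth = list(mode = spec$surface_mode,
                    synergy_strength = spec$synergy_strength,
                    hill_a = pa, hill_b = pb, viability_true = v_true,
                    noise_sd = spec$noise_sd))
}

#' Generate an RPPA matrix with planted differential antibodies
#'
#' Samples cover the full design: two sensitivity classes x two treatments
#' (drug/vehicle) x two timepoints, `n_per_arm` samples each. Antibody
#' values are the antibody's Gaussian baseline plus noise; the first
#' `n_planted` antibodies are shifted by `effect_size` in the drug arm of
#' the designated timepoints and classes.
#'
#' @param spec A [generator_spec()]; see the `rppa_spec` argument of
#'   [generator_spec()].
#' @return List with `rppa` (an [rppa_matrix()], all antibodies marked
#'   validated) and `truth` (planted antibody names and strata).
#' @export
gen_rppa_matrix <- function(spec) {
  rs <- spec$rppa_spec
  set.seed(spec$seed)
  antibodies <- sprintf("ab%04d", seq_len(rs$n_antibodies))
  design <- expand.grid(
    replicate = seq_len(rs$n_per_arm),
    treatment = c("drug", "vehicle"),
    timepoint = c("24h", "72h"),
    sensitivity = c("sensitive", "resistant"),
    stringsAsFactors = FALSE
  )
  design$cell_line <- paste0(substr(design$sensitivity, 1, 1), design$replicate)
  design$sample <- sprintf("%s_%s_%s_r%d", design$cell_line, design$treatment,
                           design$timepoint, design$replicate)
  baseline <- stats::rnorm(rs$n_antibodies, 0, 1)
  values <- baseline +
    matrix(stats::rnorm(rs$n_antibodies * nrow(design), 0, rs$noise_sd),
           rs$n_antibodies, nrow(design))
  planted <- antibodies[seq_len(rs$n_planted)]
  hit_cols <- design$treatment == "drug" &
    design$timepoint %in% rs$planted_timepoints &
    design$sensitivity %in% rs$planted_classes
  if (rs$n_planted > 0 && any(hit_cols)) {
    values[seq_len(rs$n_planted), hit_cols] <-
      values[seq_len(rs$n_planted), hit_cols] + rs$effect_size
  }
  rownames(values) <- antibodies
  colnames(values) <- design$sample
  rppa <- rppa_matrix(
    values,
    antibody_meta = data.frame(antibody = antibodies, status = "validated",
                               stringsAsFactors = FALSE),
    sample_meta = design[, c("sample", "cell_line", "sensitivity",
                             "treatment", "timepoint")]
  )
  list(rppa = rppa,
       truth = list(planted = planted,
                    planted_timepoints = rs$planted_timepoints,
                    planted_classes = rs$planted_classes,
                    effect_size = rs$effect_size, noise_sd = rs$noise_sd))
}

#' Generate xenograft tumor-growth trajectories with known truth
#'
#' Each animal grows exponentially from the baseline volume with a small
#' between-animal rate perturbation; the group's treatment multiplier is
#' applied to the volume after the treatment-start day, and multiplicative
#' log-normal measurement noise is added. Volumes are converted to caliper
#' (length, width) pairs under the `width = 0.8 * length` convention, so
#' `tumor_volume()` recovers them via length * width^2 / 2.
#'
#' @param spec A [generator_spec()]; see the `growth_spec` argument of
#'   [generator_spec()].
#' @param groups data.frame with columns `group`, `n`, `multiplier`
#'   (default: vehicle n=8 multiplier 1, treatment n=6 multiplier from
#'   `growth_spec`).
#' @param days Measurement days (default 0 to 28 every 2 days).
#' @return List with `measurements` (animal_id, day, length, width, group)
#'   and `truth`.
#' @export
gen_growth_curves <- function(spec, groups = NULL, days = seq(0, 28, by = 2)) {
  gs <- spec$growth_spec
  if (is.null(groups)) {
    groups <- data.frame(group = c("vehicle", "treatment"), n = c(8L, 6L),
                         multiplier = c(1, gs$treatment_multiplier),
                         stringsAsFactors = FALSE)
  }
  set.seed(spec$seed)
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    for (i in seq_len(groups$n[g])) {
      id <- sprintf("%s_%02d", groups$group[g], i)
      rate <- gs$growth_rate + stats::rnorm(1, 0, gs$growth_rate_sd)
      vol <- gs$baseline_volume * exp(rate * days)
      treated <- days > gs$treatment_start_day
      vol[treated] <- vol[treated] * groups$multiplier[g]
      vol <- vol * exp(stats::rnorm(length(days), 0, gs$measurement_noise_sd))
      len <- (vol / 0.32)^(1 / 3)
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = id, day = days, length = len, width = 0.8 * len,
        group = groups$group[g], stringsAsFactors = FALSE
      )
    }
  }
  list(measurements = do.call(rbind, rows),
       truth = list(groups = groups, growth_spec = gs, days = days))
}
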