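#' Default GP surface fit options
#'
#' @param zero_dose_offset Pseudo-dose added before the log10 transform so
#'   that zero doses get a finite log coordinate. `NULL` (default) uses
#'   one tenth of the smallest nonzero dose, per axis.
#' @param restarts Number of deterministic multi-start initializations.
#' @param seed Integer seed recorded for provenance (the optimizer itself is
#'   deterministic).
#' @param jitter Diagonal jitter added to the kernel matrix for numerical
#'   stability.
#' @return List of options for [fit_gp_surface()].
#' @export
gp_fit_options <- function(zero_dose_offset = NULL, restarts = 6, seed = 1L,
                           jitter = 1e-10) {
  list(zero_dose_offset = zero_dose_offset, restarts = restarts, seed = seed,
       jitter = jitter)
}

# squared-exponential (RBF) kernel with per-axis length-scales, on a matrix
# of 2-column inputs; returns the noise-free covariance
rbf_kernel <- function(x1, x2, sf2, ls) {
  d1 <- outer(x1[, 1], x2[, 1], "-") / ls[1]
  d2 <- outer(x1[, 2], x2[, 2], "-") / ls[2]
  sf2 * exp(-0.5 * (d1^2 + d2^2))
}

# negative log marginal likelihood and its gradient in
# theta = (log sf2, log ls1, log ls2, log sn2), for centered targets yc
gp_nll <- function(theta, x, yc, jitter) {
  n <- length(yc)
  sf2 <- exp(theta[1]); ls <- exp(theta[2:3]); sn2 <- exp(theta[4])
  d1 <- outer(x[, 1], x[, 1], "-") / ls[1]
  d2 <- outer(x[, 2], x[, 2], "-") / ls[2]
  Kf <- sf2 * exp(-0.5 * (d1^2 + d2^2))
  K <- Kf + diag(sn2 + jitter, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, 4)))
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  nll <- 0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(ch)
  W <- alpha %*% t(alpha) - Kinv          # d(logML)/dK = W/2
  g <- c(
    0.5 * sum(W * Kf),                    # d/d log sf2
    0.5 * sum(W * (Kf * d1^2)),           # d/d log ls1
    0.5 * sum(W * (Kf * d2^2)),           # d/d log ls2
    0.5 * sum(diag(W)) * sn2              # d/d log sn2
  )
  list(value = nll, grad = -g)
}

#' Fit a Gaussian-process model to a combination dose-response surface
#'
#' Exact GP regression of normalized viability on the two log10-dose
#' coordinates, with a squared-exponential (RBF) kernel, per-axis
#' length-scales, independent Gaussian noise, and a constant prior mean at
#' the average observed viability. Kernel hyperparameters maximize the exact
#' log marginal likelihood by gradient-based optimization (analytic
#' gradients, L-BFGS-B) from a deterministic grid of starting values; the
#' best start is kept. Zero doses are placed on the log scale via a small
#' pseudo-dose offset.
#'
#' A grid with (numerically) constant viabilities is flagged `degenerate`
#' and modelled with near-zero signal variance: the posterior mean is the
#' constant.
#'
#' @param grid A [combination_grid()], typically 7x7.
#' @param opts Options from [gp_fit_options()].
#' @return A `gp_surface` object holding the grid, kernel parameters
#'   (`signal_var`, `length_scales`, `noise_var`), the log marginal
#'   likelihood at the optimum (`log_evidence`), and the factorizations
#'   needed for prediction.
#' @export
fit_gp_surface <- function(grid, opts = gp_fit_options()) {
  if (!inherits(grid, "combination_grid")) stop("grid must be a combination_grid")
  off <- opts$zero_dose_offset
  off_a <- if (is.null(off)) min(grid$doses_a[grid$doses_a > 0]) / 10 else off
  off_b <- if (is.null(off)) min(grid$doses_b[grid$doses_b > 0]) / 10 else off

  xa <- log10(grid$doses_a + off_a)
  xb <- log10(grid$doses_b + off_b)
  x <- as.matrix(expand.grid(a = xa, b = xb))   # row-major over doses_a
  y <- as.numeric(grid$viabilities)             # column-major matches expand.grid
  n <- length(y)
  m <- mean(y)
  yc <- y - m
  vy <- stats::var(y)

  degenerate <- !is.finite(vy) || vy < 1e-12
  if (degenerate) {
    theta <- log(c(1e-10, 1, 1, 1e-10))
    nll <- gp_nll(theta, x, yc, opts$jitter)
    best <- list(par = theta, value = nll$value)
  } else {
    sdx <- c(stats::sd(x[, 1]), stats::sd(x[, 2]))
    start_grid <- expand.grid(lmul = c(0.3, 1, 3), snf = c(1e-4, 1e-2))
    start_grid <- start_grid[seq_len(min(nrow(start_grid), opts$restarts)), ]
    lower <- log(c(1e-10, sdx * 1e-2, 1e-8))
    upper <- log(c(1e3 * vy + 1, sdx * 1e3, vy + 1e-8))
    best <- NULL
    for (i in seq_len(nrow(start_grid))) {
      theta0 <- log(c(vy, sdx * start_grid$lmul[i], vy * start_grid$snf[i]))
      theta0 <- pmin(pmax(theta0, lower), upper)
      res <- tryCatch(
        stats::optim(theta0,
                     fn = function(th) gp_nll(th, x, yc, opts$jitter)$value,
                     gr = function(th) gp_nll(th, x, yc, opts$jitter)$grad,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL
      )
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
    if (is.null(best)) stop("GP hyperparameter optimization failed")
  }

  sf2 <- exp(best$par[1]); ls <- exp(best$par[2:3]); sn2 <- exp(best$par[4])
  K <- rbf_kernel(x, x, sf2, ls) + diag(sn2 + opts$jitter, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))

  structure(
    list(grid = grid, x = x, y = y, mean_const = m,
         signal_var = sf2, length_scales = ls, noise_var = sn2,
         log_evidence = -best$value, degenerate = degenerate,
         zero_dose_offset = c(a = off_a, b = off_b),
         chol = ch, alpha = alpha, jitter = opts$jitter),
    class = "gp_surface"
  )
}

#' @export
print.gp_surface <- function(x, ...) {
  cat(sprintf(
    "<gp_surface> %s x %s: signal var %.3g, length-scales (%.3g, %.3g), noise var %.3g, logML %.4g%s\n",
    x$grid$drug_a, x$grid$drug_b, x$signal_var, x$length_scales[1],
    x$length_scales[2], x$noise_var, x$log_evidence,
    if (x$degenerate) " [degenerate: constant grid]" else ""))
  invisible(x)
}

# internal: posterior mean/sd of viability at dose pairs (vectorized);
# range checking against the measured dose box
gp_posterior <- function(surface, conc_a, conc_b, check_range = TRUE) {
  g <- surface$grid
  if (check_range) {
    bad <- conc_a < 0 | conc_a > max(g$doses_a) |
           conc_b < 0 | conc_b > max(g$doses_b)
    if (any(bad)) {
      stop("query outside the measured dose range; prediction is confined ",
           "to the dose box [0, ", max(g$doses_a), "] x [0, ",
           max(g$doses_b), "] uM")
    }
  }
  xs <- cbind(log10(conc_a + unname(surface$zero_dose_offset["a"])),
              log10(conc_b + unname(surface$zero_dose_offset["b"])))
  ks <- rbf_kernel(surface$x, xs, surface$signal_var, surface$length_scales)
  mu <- surface$mean_const + unname(drop(t(ks) %*% surface$alpha))
  v <- forwardsolve(t(surface$chol), ks)
  var <- pmax(surface$signal_var - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(var))
}

#' Predict inhibition from a fitted GP surface
#'
#' Posterior mean inhibition (1 - posterior mean viability) and predictive
#' standard deviation at a dose pair. Queries outside the measured dose box
#' are refused: the surface model is trusted only within the measured
#' dose range.
#'
#' @param surface A `gp_surface` from [fit_gp_surface()].
#' @param conc_a,conc_b Doses in uM (vectors allowed, recycled pairwise).
#' @return List with `inhibition` and `sd`.
#' @export
predict_inhibition <- function(surface, conc_a, conc_b) {
  post <- gp_posterior(surface, conc_a, conc_b)
  list(inhibition = 1 - post$mean, sd = post$sd)
}

#' Extract an iso-effect contour from a GP surface
#'
#' Traces the set of dose pairs whose posterior-mean inhibition equals
#' `effect_level`, by bisection along rays from the dose origin through the
#' measured dose box. If the maximum posterior-mean inhibition over the
#' measured range is below `effect_level` the contour is reported as not
#' reached and no points are returned (downstream, no combination indices
#' are computed for that level).
#'
#' @param surface A `gp_surface`.
#' @param effect_level Inhibition fraction in (0, 1).
#' @param n_rays Number of rays (default 50).
#' @param tol Bisection tolerance on inhibition (default 1e-3).
#' @return An `iso_effect_contour`: list with `effect_level`, `reached`, and
#'   a data.frame `points` with columns `conc_a`, `conc_b`.
#' @export
find_isoeffect <- function(surface, effect_level, n_rays = 50, tol = 1e-3) {
  if (effect_level <= 0 || effect_level >= 1) {
    stop("effect_level must be in (0, 1)")
  }
  g <- surface$grid
  amax <- max(g$doses_a); bmax <- max(g$doses_b)

  # max inhibition over a dense grid (uniform in the GP input space)
  na <- 41; nb <- 41
  qa <- 10^seq(log10(surface$zero_dose_offset["a"]),
               log10(amax + surface$zero_dose_offset["a"]), length.out = na) -
    surface$zero_dose_offset["a"]
  qb <- 10^seq(log10(surface$zero_dose_offset["b"]),
               log10(bmax + surface$zero_dose_offset["b"]), length.out = nb) -
    surface$zero_dose_offset["b"]
  qa <- pmin(pmax(qa, 0), amax); qb <- pmin(pmax(qb, 0), bmax)
  dense <- expand.grid(a = qa, b = qb)
  inh <- 1 - gp_posterior(surface, dense$a, dense$b, check_range = FALSE)$mean
  if (max(inh) < effect_level) {
    return(structure(list(effect_level = effect_level, reached = FALSE,
                          points = data.frame(conc_a = numeric(0),
                                              conc_b = numeric(0))),
                     class = "iso_effect_contour"))
  }

  # rays from the origin to points spread along the far edges of the box
  k <- ceiling(n_rays / 2)
  f <- seq(0.02, 1, length.out = k)
  ends <- rbind(cbind(amax, f * bmax), cbind(f[-k] * amax, bmax))
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(ends))) {
    ray_inh <- function(t) {
      1 - gp_posterior(surface, t * ends[i, 1], t * ends[i, 2],
                       check_range = FALSE)$mean
    }
    ts <- seq(0, 1, length.out = 64)
    vals <- ray_inh(ts) - effect_level
    cross <- which(vals[-1] * vals[-length(vals)] <= 0 &
                     (vals[-1] != vals[-length(vals)]))
    if (length(cross) == 0) next
    lo <- ts[cross[1]]; hi <- ts[cross[1] + 1]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      vm <- ray_inh(mid) - effect_level
      if (abs(vm) < tol) { lo <- hi <- mid; break }
      if (sign(vm) == sign(ray_inh(lo) - effect_level)) lo <- mid else hi <- mid
    }
    t0 <- (lo + hi) / 2
    pts <- rbind(pts, c(t0 * ends[i, 1], t0 * ends[i, 2]))
  }
  structure(
    list(effect_level = effect_level, reached = nrow(pts) > 0,
         points = data.frame(conc_a = pts[, 1], conc_b = pts[, 2])),
    class = "iso_effect_contour"
  )
}

#' @export
print.iso_effect_contour <- function(x, ...) {
  cat(sprintf("<iso_effect_contour> %.0f%% inhibition: %s (%d points)\n",
              100 * x$effect_level,
              if (x$reached) "reached" else "not reached", nrow(x$points)))
  invisible(x)
}
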