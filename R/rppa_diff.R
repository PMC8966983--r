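#' Construct an RPPA matrix object
#'
#' Container for a normalized-log2 antibody x sample matrix with antibody
#' validation status and per-sample design metadata.
#'
#' @param values Numeric matrix, antibodies in rows (rownames required),
#'   samples in columns (colnames required). No missing values.
#' @param antibody_meta data.frame with columns `antibody` and `status`
#'   (`"validated"`, `"caution"`, or other), one row per matrix row.
#' @param sample_meta data.frame with columns `sample`, `cell_line`,
#'   `sensitivity` (`"sensitive"`/`"resistant"`), `treatment`
#'   (`"drug"`/`"vehicle"`), `timepoint` (`"24h"`/`"72h"`), one row per
#'   matrix column.
#' @return An `rppa_matrix` object.
#' @export
rppa_matrix <- function(values, antibody_meta, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have antibody rownames and sample colnames")
  }
  if (any(is.na(values))) stop("RPPA values must have no missing entries")
  if (!all(c("antibody", "status") %in% names(antibody_meta))) {
    stop("antibody_meta needs columns antibody, status")
  }
  need <- c("sample", "cell_line", "sensitivity", "treatment", "timepoint")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta needs columns ", paste(need, collapse = ", "))
  }
  if (!setequal(antibody_meta$antibody, rownames(values)) ||
      nrow(antibody_meta) != nrow(values)) {
    stop("antibody_meta must cover every antibody exactly once")
  }
  if (!setequal(sample_meta$sample, colnames(values)) ||
      nrow(sample_meta) != ncol(values)) {
    stop("sample_meta must cover every sample exactly once")
  }
  if (any(is.na(sample_meta[need]))) stop("sample metadata must be complete")
  antibody_meta <- antibody_meta[match(rownames(values), antibody_meta$antibody), ]
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ]
  structure(list(values = values, antibody_meta = antibody_meta,
                 sample_meta = sample_meta),
            class = "rppa_matrix")
}

#' @export
print.rppa_matrix <- function(x, ...) {
  cat(sprintf("<rppa_matrix> %d antibodies x %d samples (%d validated)\n",
              nrow(x$values), ncol(x$values),
              sum(x$antibody_meta$status == "validated")))
  invisible(x)
}

#' Restrict an RPPA matrix to validated antibodies
#'
#' Antibodies whose status is not `"validated"` (including those flagged
#' "use with caution") are dropped before any differential analysis.
#'
#' @param rppa An [rppa_matrix()].
#' @return The filtered `rppa_matrix`; the number of removed antibodies is
#'   reported via `message()`.
#' @export
filter_validated <- function(rppa) {
  keep <- rppa$antibody_meta$status == "validated"
  if (!any(keep)) stop("no validated antibodies; nothing to analyze")
  removed <- sum(!keep)
  if (removed > 0) {
    message(removed, " non-validated antibod",
            if (removed == 1) "y" else "ies", " removed")
  }
  rppa_matrix(rppa$values[keep, , drop = FALSE],
              rppa$antibody_meta[keep, , drop = FALSE],
              rppa$sample_meta)
}

# Newton solve of trigamma(x) = y, vectorized (monotone decreasing trigamma)
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

# moment-matched scaled-inverse-chi-square prior for variances:
# log s^2 corrected for its chi-square bias, then matched on mean/variance
fit_variance_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-12)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess spread beyond chi-square sampling noise: infinite prior df,
    # pooled variance as the common value (fixed point: identical sample
    # variances shrink to themselves)
    df_prior <- Inf
    s2_prior <- mean(s2)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Empirical-Bayes moderated t-test on an RPPA matrix
#'
#' Per-antibody drug-vs-vehicle comparison of normalized log2 affinities
#' within a design stratum. Residual variances are shrunk toward a common
#' prior estimated from the across-antibody variance distribution
#' (moment matching of the log sample variances to a scaled inverse
#' chi-square prior), stabilizing inference at small sample sizes:
#'
#' `s2_tilde = (d0 * s0^2 + d * s^2) / (d0 + d)`,
#' `t_mod = log_fc / (s_tilde * sqrt(1/n1 + 1/n2))`,
#'
#' with two-sided p-values from a t distribution on `d + d0` degrees of
#' freedom. With `prior_df = 0` no shrinkage is applied and `t_mod` is the
#' ordinary equal-variance two-sample t.
#'
#' @param rppa An [rppa_matrix()] (typically after [filter_validated()]).
#' @param stratum Optional named list restricting samples by metadata, e.g.
#'   `list(timepoint = "72h")` or `list(sensitivity = "resistant")`.
#' @param prior_df `NULL` (default) to estimate the prior degrees of freedom
#'   from the data; `0` for the ordinary t; a positive number to fix them.
#' @param paired If `TRUE`, drug and vehicle samples are paired by cell line
#'   within the stratum and a one-sample moderated t is applied to the
#'   per-line differences.
#' @param fdr_threshold Significance threshold on the BH-adjusted p
#'   (default 0.05).
#' @return data.frame with one row per antibody: `antibody`, `log_fc`
#'   (drug - vehicle), `t_mod`, `p`, `fdr`, `significant`, `direction`.
#' @export
moderated_t_test <- function(rppa, stratum = NULL, prior_df = NULL,
                             paired = FALSE, fdr_threshold = 0.05) {
  meta <- rppa$sample_meta
  keep <- rep(TRUE, nrow(meta))
  for (nm in names(stratum)) {
    if (!nm %in% names(meta)) stop("unknown stratum variable: ", nm)
    keep <- keep & meta[[nm]] %in% stratum[[nm]]
  }
  meta <- meta[keep, , drop = FALSE]
  vals <- rppa$values[, meta$sample, drop = FALSE]
  drug <- meta$treatment == "drug"
  veh <- meta$treatment == "vehicle"

  if (paired) {
    lines <- intersect(unique(meta$cell_line[drug]), unique(meta$cell_line[veh]))
    if (length(lines) < 2) stop("paired analysis needs >= 2 complete pairs")
    diffs <- vapply(lines, function(l) {
      rowMeans(vals[, drug & meta$cell_line == l, drop = FALSE]) -
        rowMeans(vals[, veh & meta$cell_line == l, drop = FALSE])
    }, numeric(nrow(vals)))
    n <- length(lines)
    log_fc <- rowMeans(diffs)
    s2 <- apply(diffs, 1, stats::var)
    df_resid <- n - 1
    se_unit <- 1 / sqrt(n)
  } else {
    n1 <- sum(drug); n2 <- sum(veh)
    if (n1 < 2 || n2 < 2) {
      stop("each arm needs >= 2 samples within the stratum (have ",
           n1, " drug, ", n2, " vehicle)")
    }
    m1 <- rowMeans(vals[, drug, drop = FALSE])
    m2 <- rowMeans(vals[, veh, drop = FALSE])
    log_fc <- m1 - m2
    ss1 <- rowSums((vals[, drug, drop = FALSE] - m1)^2)
    ss2 <- rowSums((vals[, veh, drop = FALSE] - m2)^2)
    df_resid <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / df_resid
    se_unit <- sqrt(1 / n1 + 1 / n2)
  }

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, df_resid)
  } else if (prior_df == 0) {
    prior <- list(df_prior = 0, s2_prior = 0)
  } else {
    e <- log(pmax(s2, 1e-12)) - digamma(df_resid / 2) + log(df_resid / 2)
    prior <- list(df_prior = prior_df,
                  s2_prior = exp(mean(e) + digamma(prior_df / 2) -
                                   log(prior_df / 2)))
  }
  d0 <- prior$df_prior
  s2_tilde <- if (is.infinite(d0)) {
    rep(prior$s2_prior, length(s2))
  } else {
    (d0 * prior$s2_prior + df_resid * s2) / (d0 + df_resid)
  }
  t_mod <- log_fc / (sqrt(s2_tilde) * se_unit)
  df_total <- df_resid + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  fdr <- bh_adjust(p)
  data.frame(
    antibody = rownames(rppa$values),
    log_fc = log_fc, t_mod = t_mod, p = p, fdr = fdr,
    significant = fdr < fdr_threshold,
    direction = ifelse(log_fc >= 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement; the output is in the
#' same order as the input.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Direction-stratified overlap of significant antibodies across strata
#'
#' For each direction (increased/decreased affinity), reports the
#' antibodies significant in every stratum (shared) and those unique to
#' each, mirroring the Venn-diagram comparison of, e.g., 24h vs 72h
#' treatment or sensitive vs resistant lines.
#'
#' @param results_by_stratum Named list (>= 2 entries) of differential
#'   result tables from [moderated_t_test()].
#' @return List with one element per direction (`up`, `down`), each holding
#'   `shared` and `unique_<stratum>` identifier vectors, plus a `counts`
#'   data.frame summary.
#' @export
set_comparison <- function(results_by_stratum) {
  if (length(results_by_stratum) < 2 || is.null(names(results_by_stratum))) {
    stop("need a named list of >= 2 strata")
  }
  out <- list()
  counts <- list()
  for (dir in c("up", "down")) {
    sets <- lapply(results_by_stratum, function(r) {
      r$antibody[r$significant & r$direction == dir]
    })
    shared <- Reduce(intersect, sets)
    uniq <- lapply(seq_along(sets), function(i) {
      setdiff(sets[[i]], unique(unlist(sets[-i])))
    })
    names(uniq) <- paste0("unique_", names(sets))
    out[[dir]] <- c(list(shared = shared), uniq)
    counts[[dir]] <- data.frame(
      direction = dir,
      stratum = c("shared", names(sets)),
      n = c(length(shared), lengths(uniq)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out$counts <- do.call(rbind, counts)
  rownames(out$counts) <- NULL
  out
}
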