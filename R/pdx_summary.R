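#' Validate caliper tumor measurements
#'
#' Checks a measurement table (`animal_id`, `day`, `length`, `width`,
#' `group`) and enforces the caliper convention width <= length, swapping
#' the two with a warning where violated.
#'
#' @param measurements data.frame with columns `animal_id`, `day`,
#'   `length`, `width`, `group` (lengths in mm).
#' @return The validated (possibly swapped) measurement table.
#' @export
tumor_measurements <- function(measurements) {
  need <- c("animal_id", "day", "length", "width", "group")
  if (!all(need %in% names(measurements))) {
    stop("measurements need columns ", paste(need, collapse = ", "))
  }
  if (any(measurements$length <= 0) || any(measurements$width <= 0)) {
    stop("length and width must be > 0")
  }
  swap <- measurements$width > measurements$length
  if (any(swap)) {
    warning(sum(swap), " measurement(s) had width > length; axes swapped")
    tmp <- measurements$length[swap]
    measurements$length[swap] <- measurements$width[swap]
    measurements$width[swap] <- tmp
  }
  measurements
}

#' Tumor volume from caliper length and width
#'
#' The standard ellipsoid approximation `volume = length * width^2 / 2`.
#'
#' @param length,width Caliper measurements in mm (> 0).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) stop("length and width must be > 0")
  length * width^2 / 2
}

#' Percent tumor-volume reduction versus control
#'
#' `100 * (mean_control - mean_treated) / mean_control`.
#'
#' @param mean_control Mean control (vehicle) volume, mm^3 (> 0).
#' @param mean_treated Mean treated volume, mm^3.
#' @return Percent reduction (negative if the treated group is larger).
#' @export
percent_reduction <- function(mean_control, mean_treated) {
  if (any(mean_control <= 0)) stop("mean_control must be > 0")
  100 * (mean_control - mean_treated) / mean_control
}

#' Day-wise group growth summaries
#'
#' Mean, SD and number of surviving animals per group and day, computed
#' over the animals measured on that day (animals removed mid-study simply
#' stop contributing; no imputation).
#'
#' @param measurements Validated table from [tumor_measurements()].
#' @return data.frame with `group`, `day`, `mean_volume`, `sd_volume`, `n`.
#' @export
growth_summary <- function(measurements) {
  m <- tumor_measurements(measurements)
  m$volume <- tumor_volume(m$length, m$width)
  agg <- aggregate(volume ~ group + day, data = m,
                   FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                       n = length(v)))
  out <- data.frame(group = agg$group, day = agg$day,
                    mean_volume = agg$volume[, "mean"],
                    sd_volume = agg$volume[, "sd"],
                    n = as.integer(agg$volume[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$group, out$day), ]
}

#' Compare endpoint tumor volumes between groups
#'
#' Two-sample Student's t-test (equal variances by default, Welch optional)
#' of each treatment group against the vehicle group.
#'
#' @param volumes data.frame with columns `animal_id`, `group`, `volume`
#'   (one endpoint volume per animal).
#' @param vehicle Label of the control group (default `"vehicle"`).
#' @param var_equal Equal-variance Student's t (default `TRUE`); `FALSE`
#'   gives Welch's t.
#' @return data.frame with one row per treatment group: `group`, `n`,
#'   `n_vehicle`, `mean_volume`, `mean_vehicle`, `percent_reduction`,
#'   `t`, `df`, `p`.
#' @export
compare_groups <- function(volumes, vehicle = "vehicle", var_equal = TRUE) {
  if (!all(c("group", "volume") %in% names(volumes))) {
    stop("volumes need columns group, volume")
  }
  if (!vehicle %in% volumes$group) stop("no '", vehicle, "' group present")
  ctrl <- volumes$volume[volumes$group == vehicle]
  groups <- setdiff(unique(volumes$group), vehicle)
  if (length(ctrl) < 2) stop("vehicle group has < 2 animals")
  rows <- lapply(groups, function(g) {
    trt <- volumes$volume[volumes$group == g]
    if (length(trt) < 2) stop("group '", g, "' has < 2 animals")
    tt <- stats::t.test(trt, ctrl, var.equal = var_equal)
    data.frame(group = g, n = length(trt), n_vehicle = length(ctrl),
               mean_volume = mean(trt), mean_vehicle = mean(ctrl),
               percent_reduction = percent_reduction(mean(ctrl), mean(trt)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
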