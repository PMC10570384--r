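#' Per-cell red-to-green ratio
#'
#' Computes the post-photoconversion red-to-green ratio (RGR), the per-cell
#' activity readout. The standard variant is `r_post / g_post` on corrected
#' intensities. The paired variant, used for preparations where pre-PC red
#' puncta bias the red channel (e.g. PV-cre lines), is
#' `(r_post - r_pre) / g_post`: subtracting the same cell's pre-PC red
#' removes any static red offset (including autofluorescence), so no
#' separate offset correction is applied there.
#'
#' @param g_post,r_post Corrected post-PC green and red per-cell means.
#' @param r_pre Corrected pre-PC red means (paired variant only; matched to
#'   the same cells).
#' @param variant `"standard"` or `"paired"`.
#' @return Numeric vector of RGR values; cells with non-positive green are
#'   `NA` (flagged out by QC rather than clipped).
#' @export
compute_rgr <- function(g_post, r_post, r_pre = NULL,
                        variant = c("standard", "paired")) {
  variant <- match.arg(variant)
  stopifnot(length(g_post) == length(r_post))
  num <- if (variant == "paired") {
    if (is.null(r_pre)) stop("paired variant requires r_pre")
    stopifnot(length(r_pre) == length(r_post))
    r_post - r_pre
  } else {
    r_post
  }
  out <- ifelse(g_post > 0, num / g_post, NA_real_)
  as.numeric(out)
}

#' Summarize RGR distributions per region
#'
#' Per-region summary of a per-cell RGR table: cell count, median, mean,
#' sample variance (n - 1 denominator), the 25th/75th and 5th/95th
#' percentiles (linear interpolation), and the 5-95 percentile range used as
#' a population activity-range metric.
#'
#' @param rgr Numeric vector of per-cell RGR values (NAs dropped).
#' @param region Region label per cell; `NULL` summarizes all cells as one
#'   region `"all"`.
#' @return data.frame with one row per region: `region`, `n_cells`,
#'   `median`, `mean`, `variance`, `p25`, `p75`, `p5`, `p95`, `range_5_95`.
#' @export
summarize_region <- function(rgr, region = NULL) {
  if (is.null(region)) region <- rep("all", length(rgr))
  stopifnot(length(rgr) == length(region))
  keep <- !is.na(rgr)
  rgr <- rgr[keep]; region <- as.character(region)[keep]
  if (length(rgr) == 0) stop("no cells to summarize")
  regs <- sort(unique(region))
  rows <- lapply(regs, function(rg) {
    v <- rgr[region == rg]
    q <- stats::quantile(v, c(0.05, 0.25, 0.75, 0.95), type = 7, names = FALSE)
    data.frame(region = rg, n_cells = length(v),
               median = stats::median(v), mean = mean(v),
               variance = if (length(v) > 1) stats::var(v) else NA_real_,
               p25 = q[2], p75 = q[3], p5 = q[1], p95 = q[4],
               range_5_95 = q[4] - q[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity index d' between two RGR distributions
#'
#' Standardized separation between two populations of RGR values:
#' \deqn{d' = \frac{\bar{x}_A - \bar{x}_B}{\sqrt{0.5 (s^2_A + s^2_B)}}}
#' with sample means and, by default, sample variances (n - 1 denominator).
#'
#' @param a,b Numeric vectors (>= 2 values each; NAs dropped).
#' @param var_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return d' as a numeric scalar. If both groups are constant the pooled
#'   variance is zero: equal means give 0; unequal means give signed `Inf`
#'   with a warning and attribute `degenerate = TRUE`.
#' @export
dprime <- function(a, b, var_type = c("sample", "population")) {
  var_type <- match.arg(var_type)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per group")
  va <- stats::var(a); vb <- stats::var(b)
  if (var_type == "population") {
    va <- va * (length(a) - 1) / length(a)
    vb <- vb * (length(b) - 1) / length(b)
  }
  pooled <- 0.5 * (va + vb)
  delta <- mean(a) - mean(b)
  if (pooled == 0) {
    if (delta == 0) return(0)
    warning("zero pooled variance with unequal means; d' is infinite")
    out <- sign(delta) * Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  delta / sqrt(pooled)
}

#' Photoconversion light-dose arithmetic
#'
#' Converts an illumination protocol (power, circular aperture, cycle
#' duration, number of cycles) into intensity and cumulative light dose.
#' Intensity is power divided by the illumination cross-section; the dose of
#' one cycle is intensity times cycle duration; the cumulative dose is
#' linear in the number of cycles. With power in mW, aperture in mm and time
#' in s, intensity is in mW/mm^2 (also reported in mW/cm^2) and doses are in
#' mJ/mm^2 -- the numeric scale on which protocol dose figures are quoted.
#'
#' @param power Illumination power at the sample plane, mW (> 0).
#' @param aperture_diameter Diameter of the illuminated circle, mm (> 0).
#' @param cycle_duration Illumination time per cycle, s (> 0).
#' @param n_cycles Number of illumination cycles (>= 0).
#' @return List with `intensity_mw_mm2`, `intensity_mw_cm2`,
#'   `per_cycle_dose`, `cumulative_dose` (mJ/mm^2), and the inputs.
#' @export
light_dose <- function(power, aperture_diameter, cycle_duration = 1,
                       n_cycles = 1) {
  stopifnot(power > 0, aperture_diameter > 0, cycle_duration > 0,
            n_cycles >= 0)
  area_mm2 <- pi * (aperture_diameter / 2)^2
  intensity <- power / area_mm2
  per_cycle <- intensity * cycle_duration
  list(intensity_mw_mm2 = intensity,
       intensity_mw_cm2 = intensity * 100,
       per_cycle_dose = per_cycle,
       cumulative_dose = per_cycle * n_cycles,
       power = power, aperture_diameter = aperture_diameter,
       cycle_duration = cycle_duration, n_cycles = n_cycles)
}

#' Number of illumination cycles needed for a target dose
#'
#' @param target_dose Target cumulative dose in mJ/mm^2.
#' @param per_cycle_dose Dose delivered by one cycle, mJ/mm^2 (e.g. from
#'   [light_dose()]).
#' @return Smallest integer number of cycles whose cumulative dose reaches
#'   the target.
#' @export
cycles_for_dose <- function(target_dose, per_cycle_dose) {
  stopifnot(target_dose >= 0, per_cycle_dose > 0)
  as.integer(ceiling(target_dose / per_cycle_dose))
}
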