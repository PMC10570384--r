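#' Optical nuisance model for synthetic acquisitions
#'
#' Bundles the detector and tissue parameters that corrupt a rendered
#' two-channel stack: per-channel dark current, the fraction of green signal
#' leaking into the red channel (spectral contamination), a per-hemisphere
#' red-channel autofluorescence offset (the cranial-window angle differs
#' between hemispheres, so each window contributes its own baseline), depth
#' attenuation, and a PMT-style noise model.
#'
#' @param dark_green,dark_red Dark-current offsets in counts (>= 0).
#' @param contamination_ratio Fraction of green signal detected in the red
#'   channel (rho, >= 0).
#' @param autofluor_intercept Named numeric vector of red autofluorescence
#'   offsets in counts, one entry per hemisphere (e.g. `c(L = 3, R = 6)`).
#' @param depth_attenuation Exponential attenuation coefficient per
#'   micrometre of depth; the signal of a cell at depth z is multiplied by
#'   `exp(-depth_attenuation * z)` in both channels. Default 0 (no
#'   attenuation across superficial layer II/III).
#' @param depth_attenuation_red Optional red-channel-specific coefficient;
#'   `NULL` (default) uses `depth_attenuation` for both channels.
#' @param shot_noise_scale Variance of signal-dependent (shot-like) noise per
#'   unit signal; Gaussian approximation to Poisson photon noise.
#' @param read_noise_sd Standard deviation of additive read noise in counts.
#' @return An object of class `campari_optical` (a list of the parameters).
#' @export
optical_model <- function(dark_green = 5, dark_red = 8,
                          contamination_ratio = 0.12,
                          autofluor_intercept = c(L = 3, R = 6),
                          depth_attenuation = 0,
                          depth_attenuation_red = NULL,
                          shot_noise_scale = 0.5, read_noise_sd = 1) {
  stopifnot(dark_green >= 0, dark_red >= 0, contamination_ratio >= 0,
            depth_attenuation >= 0, shot_noise_scale >= 0, read_noise_sd >= 0)
  if (is.null(names(autofluor_intercept))) {
    names(autofluor_intercept) <- if (length(autofluor_intercept) == 1) "L" else
      stop("autofluor_intercept must be named by hemisphere")
  }
  structure(list(dark_green = dark_green, dark_red = dark_red,
                 contamination_ratio = contamination_ratio,
                 autofluor_intercept = autofluor_intercept,
                 depth_attenuation = depth_attenuation,
                 depth_attenuation_red = depth_attenuation_red,
                 shot_noise_scale = shot_noise_scale,
                 read_noise_sd = read_noise_sd),
            class = "campari_optical")
}

#' Phenomenological photoconversion model
#'
#' Maps photoconversion (PC) light dose and a cell's latent activity to the
#' fraction of sensor converted from green to red. The conversion fraction is
#' `c(dose, activity) = activity * c_max * (1 - exp(-dose / tau_dose))`:
#' zero at dose zero, saturating in dose, and proportional to activity. The
#' remaining green fluorescence is additionally bleached linearly in dose,
#' `green_factor(dose) = max(0, 1 - green_loss_slope * dose)`. Defaults are
#' calibrated so that the dose-dependent green factor falls to 60% of its
#' initial level at a dose of 300 dose units (one dose unit = 1 mW/mm^2 * 1 s
#' = 1 mJ/mm^2) and the red gain is increasing and concave in dose. This is
#' a rendering model for validation, not a claim about the sensor's
#' photophysics.
#'
#' @param c_max Maximal conversion fraction at full activity (0 < c_max <= 1).
#' @param tau_dose Dose scale of the saturating conversion, in dose units.
#' @param green_loss_slope Fractional green loss per dose unit.
#' @param red_brightness_ratio Red counts emitted per unit of converted
#'   protein, relative to the green brightness of the unconverted protein.
#' @return An object of class `campari_pc` (a list of the parameters).
#' @export
pc_model <- function(c_max = 0.3, tau_dose = 300,
                     green_loss_slope = 0.4 / 300,
                     red_brightness_ratio = 1) {
  stopifnot(c_max > 0, c_max <= 1, tau_dose > 0, green_loss_slope >= 0,
            red_brightness_ratio > 0)
  structure(list(c_max = c_max, tau_dose = tau_dose,
                 green_loss_slope = green_loss_slope,
                 red_brightness_ratio = red_brightness_ratio),
            class = "campari_pc")
}

#' Conversion fraction of the photoconversion model
#'
#' @param pc A [pc_model()].
#' @param dose Light dose in dose units (mJ/mm^2), >= 0.
#' @param activity Latent activity fraction in \[0, 1\].
#' @return Converted fraction(s) in \[0, 1\].
#' @export
pc_conversion <- function(pc, dose, activity) {
  stopifnot(all(dose >= 0), all(activity >= 0), all(activity <= 1))
  activity * pc$c_max * (1 - exp(-dose / pc$tau_dose))
}

#' Dose-dependent green retention factor
#'
#' Fraction of green fluorescence retained after the activity-independent
#' bleaching component of photoconversion illumination, clamped at zero.
#'
#' @inheritParams pc_conversion
#' @return Retention factor(s) in \[0, 1\].
#' @export
pc_green_factor <- function(pc, dose) {
  stopifnot(all(dose >= 0))
  pmax(0, 1 - pc$green_loss_slope * dose)
}

#' True red-to-green ratio implied by the generative model
#'
#' Closed-form RGR of a cell with given activity after a given dose, i.e. the
#' value the correction + extraction pipeline should recover in the noiseless
#' limit: `c * red_brightness_ratio / ((1 - c) * green_factor)`. Depth
#' attenuation cancels when it is common to both channels.
#'
#' @inheritParams pc_conversion
#' @return True RGR value(s).
#' @export
true_rgr <- function(pc, dose, activity) {
  cc <- pc_conversion(pc, dose, activity)
  gf <- pc_green_factor(pc, dose)
  cc * pc$red_brightness_ratio / ((1 - cc) * gf)
}

#' Build a synthetic scene of labelled neurons
#'
#' Places non-overlapping spherical somata in a volumetric field of view and
#' assigns each a cortical region, hemisphere, latent activity fraction and
#' baseline green brightness. Activity is drawn from a region-specific Beta
#' distribution so that, e.g., visual cortex cells are on average more active
#' than somatosensory ones during visual stimulation.
#'
#' @param n_cells Number of cells to place.
#' @param regions Character vector of region labels cells are assigned to
#'   (round-robin, so counts per region are balanced).
#' @param region_activity Named numeric vector of mean activity per region,
#'   values in (0, 1); regions absent from the vector get 0.3.
#' @param activity_concentration Beta concentration (shape1 + shape2) of the
#'   per-region activity distribution; larger means tighter.
#' @param hemisphere Hemisphere label of the acquisition ("L" or "R"); a
#'   scene corresponds to one cranial window, so all its cells share it.
#' @param dim Integer vector `c(ny, nx, nz)`: image rows, columns, z-slices.
#' @param pixel_size Lateral pixel size in micrometres.
#' @param z_step Axial step between slices in micrometres.
#' @param radius_um Somatic radius in micrometres (all cells; spheres).
#' @param base_green_meanlog,base_green_sdlog Log-normal parameters of the
#'   baseline green brightness (counts).
#' @param max_overlap Maximum tolerated fractional overlap of two somata
#'   (fraction of the sum of radii by which centres may come closer than
#'   touching); default 0 means strictly non-overlapping.
#' @param seed Optional integer seed for reproducible placement.
#' @return An object of class `campari_scene`: a list with `cells` (a
#'   data.frame with columns cell_id, x, y, z, radius, region, hemisphere,
#'   activity, base_green), the geometry fields, and `hemisphere`.
#' @export
make_scene <- function(n_cells = 120,
                       regions = c("V1", "S1"),
                       region_activity = c(V1 = 0.55, S1 = 0.25),
                       activity_concentration = 12,
                       hemisphere = "L",
                       dim = c(160L, 160L, 12L),
                       pixel_size = 1, z_step = 3,
                       radius_um = 6,
                       base_green_meanlog = log(100),
                       base_green_sdlog = 0.3,
                       max_overlap = 0, seed = NULL) {
  stopifnot(n_cells >= 1, length(dim) == 3, all(dim >= 1), radius_um > 0,
            pixel_size > 0, z_step > 0, max_overlap >= 0, max_overlap < 1)
  if (!is.null(seed)) set.seed(seed)
  ny <- dim[1]; nx <- dim[2]; nz <- dim[3]
  xmax <- nx * pixel_size; ymax <- ny * pixel_size
  zmax <- nz * z_step
  r <- radius_um
  if (2 * r >= min(xmax, ymax)) stop("field of view too small for cell radius")

  # rejection sampling of non-overlapping sphere centres
  min_dist <- (1 - max_overlap) * 2 * r
  xs <- ys <- zs <- numeric(0)
  attempts <- 0L
  while (length(xs) < n_cells) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_cells)
      stop("could not place ", n_cells, " non-overlapping cells; ",
           "reduce n_cells or radius_um")
    cx <- stats::runif(1, r, xmax - r)
    cy <- stats::runif(1, r, ymax - r)
    cz <- stats::runif(1, min(r, zmax / 2), max(zmax - r, zmax / 2))
    if (length(xs) == 0 ||
        all(sqrt((xs - cx)^2 + (ys - cy)^2 + (zs - cz)^2) >= min_dist)) {
      xs <- c(xs, cx); ys <- c(ys, cy); zs <- c(zs, cz)
    }
  }

  region <- rep_len(regions, n_cells)
  mu <- ifelse(region %in% names(region_activity),
               region_activity[region], 0.3)
  k <- activity_concentration
  activity <- stats::rbeta(n_cells, mu * k, (1 - mu) * k)
  base_green <- stats::rlnorm(n_cells, base_green_meanlog, base_green_sdlog)

  cells <- data.frame(
    cell_id = seq_len(n_cells),
    x = xs, y = ys, z = zs,
    radius = r,
    region = region,
    hemisphere = hemisphere,
    activity = activity,
    base_green = base_green,
    stringsAsFactors = FALSE
  )
  structure(list(cells = cells, dim = as.integer(dim),
                 pixel_size = pixel_size, z_step = z_step,
                 hemisphere = hemisphere, max_overlap = max_overlap),
            class = "campari_scene")
}

#' @export
print.campari_scene <- function(x, ...) {
  cat("campari_scene:", nrow(x$cells), "cells,",
      paste(x$dim, collapse = " x "),
      sprintf("voxels (%.3g um px, %.3g um z-step), hemisphere %s\n",
              x$pixel_size, x$z_step, x$hemisphere))
  cat("regions:", paste(sort(unique(x$cells$region)), collapse = ", "), "\n")
  invisible(x)
}
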