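#' Render a synthetic two-channel acquisition
#'
#' Renders a scene into a green/red volumetric image stack plus the matching
#' ground-truth label mask. Each cell is a solid sphere of uniform interior
#' intensity. With conversion fraction `c = pc_conversion(pc, dose,
#' activity)`, green retention `gf = pc_green_factor(pc, dose)` and depth
#' attenuation `att(z)`, the noiseless per-voxel means inside a cell are
#'
#' \deqn{green = base\_green (1 - c)\, gf\, att(z) + dark\_green}
#' \deqn{red = base\_green\, c\, rbr\, att(z) + \rho \cdot green\_signal +
#'   \beta + dark\_red}
#'
#' where `green_signal` is the green term before dark current, `rbr` the
#' red brightness ratio, `rho` the spectral contamination ratio and `beta`
#' the hemisphere's autofluorescence offset. Background voxels carry only
#' dark current (green) and dark current + beta (red). Noise is Gaussian
#' with variance `shot_noise_scale * signal + read_noise_sd^2` per voxel.
#'
#' @param scene A [make_scene()] scene.
#' @param optical An [optical_model()].
#' @param pc A [pc_model()].
#' @param dose Photoconversion light dose in dose units (mJ/mm^2); must be 0
#'   for `phase = "pre"` (a pre-PC acquisition has received no PC light, so
#'   the dose argument is forced to 0).
#' @param phase `"pre"` or `"post"` photoconversion.
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `campari_stack`: list with `green` and `red`
#'   numeric arrays (ny x nx x nz), integer `mask` array of cell labels,
#'   `cells` (the scene's cell table augmented with the noiseless expected
#'   means `green_true`, `red_true`, the converted-red component
#'   `red_converted_true`, and `true_rgr`), and `meta` (phase, dose,
#'   hemisphere, pixel/z geometry, slice depths).
#' @export
render_scene <- function(scene, optical = optical_model(), pc = pc_model(),
                         dose = 0, phase = c("post", "pre"), seed = NULL) {
  stopifnot(inherits(scene, "campari_scene"), dose >= 0)
  phase <- match.arg(phase)
  if (phase == "pre") dose <- 0
  if (nrow(scene$cells) == 0) stop("scene has no cells")
  check_scene_overlap(scene)
  if (!is.null(seed)) set.seed(seed)

  ny <- scene$dim[1]; nx <- scene$dim[2]; nz <- scene$dim[3]
  beta <- hemisphere_beta(optical$autofluor_intercept, scene$hemisphere)
  att_g_coef <- optical$depth_attenuation
  att_r_coef <- if (is.null(optical$depth_attenuation_red)) att_g_coef else
    optical$depth_attenuation_red

  cells <- scene$cells
  cc <- pc_conversion(pc, dose, cells$activity)
  gf <- pc_green_factor(pc, dose)
  att_g <- exp(-att_g_coef * cells$z)
  att_r <- exp(-att_r_coef * cells$z)
  green_sig <- cells$base_green * (1 - cc) * gf * att_g
  red_conv <- cells$base_green * cc * pc$red_brightness_ratio * att_r

  green <- array(0, c(ny, nx, nz))
  red <- array(0, c(ny, nx, nz))
  mask <- array(0L, c(ny, nx, nz))

  px <- scene$pixel_size; zs <- scene$z_step
  # voxel centre coordinates in micrometres
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  zc <- (seq_len(nz) - 0.5) * zs
  for (i in seq_len(nrow(cells))) {
    r <- cells$radius[i]
    ix <- which(abs(xc - cells$x[i]) <= r)
    iy <- which(abs(yc - cells$y[i]) <= r)
    iz <- which(abs(zc - cells$z[i]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xc[ix] - cells$x[i])^2
    dy2 <- (yc[iy] - cells$y[i])^2
    dz2 <- (zc[iz] - cells$z[i])^2
    d2 <- outer(outer(dy2, dx2, "+"), dz2, "+")
    inside <- d2 <= r^2
    if (!any(inside)) next
    sub <- which(inside, arr.ind = TRUE)
    idx <- cbind(iy[sub[, 1]], ix[sub[, 2]], iz[sub[, 3]])
    mask[idx] <- cells$cell_id[i]
    green[idx] <- green_sig[i]
    red[idx] <- red_conv[i]
  }

  # spectral leak of green signal, then global offsets
  red <- red + optical$contamination_ratio * green + beta + optical$dark_red
  green <- green + optical$dark_green

  if (optical$shot_noise_scale > 0 || optical$read_noise_sd > 0) {
    vg <- optical$shot_noise_scale * pmax(green - optical$dark_green, 0) +
      optical$read_noise_sd^2
    vr <- optical$shot_noise_scale * pmax(red - optical$dark_red, 0) +
      optical$read_noise_sd^2
    green <- green + stats::rnorm(length(green), 0, sqrt(vg))
    red <- red + stats::rnorm(length(red), 0, sqrt(vr))
  }

  cells$green_true <- green_sig + optical$dark_green
  cells$red_true <- red_conv + optical$contamination_ratio * green_sig +
    beta + optical$dark_red
  cells$red_converted_true <- red_conv
  cells$green_sig_true <- green_sig
  cells$true_rgr <- true_rgr(pc, dose, cells$activity)

  structure(list(
    green = green, red = red, mask = mask, cells = cells,
    meta = list(phase = phase, dose = dose, hemisphere = scene$hemisphere,
                pixel_size = px, z_step = zs,
                slice_depth = zc, dim = scene$dim)
  ), class = "campari_stack")
}

#' @export
print.campari_stack <- function(x, ...) {
  cat(sprintf("campari_stack: %s, dose %g mJ/mm^2, %d cells, %s voxels\n",
              x$meta$phase, x$meta$dose, nrow(x$cells),
              paste(x$meta$dim, collapse = " x ")))
  invisible(x)
}

# beta lookup with a helpful error for unknown hemispheres
hemisphere_beta <- function(beta, hemisphere) {
  out <- beta[as.character(hemisphere)]
  if (anyNA(out))
    stop("no autofluorescence intercept for hemisphere(s): ",
         paste(unique(hemisphere[is.na(out)]), collapse = ", "))
  unname(out)
}

# reject scenes whose cells overlap beyond the configured tolerance
check_scene_overlap <- function(scene) {
  cells <- scene$cells
  n <- nrow(cells)
  if (n < 2) return(invisible(TRUE))
  min_dist <- (1 - scene$max_overlap) * 2 * cells$radius[1]
  d <- as.matrix(stats::dist(cells[, c("x", "y", "z")]))
  diag(d) <- Inf
  bad <- which(d < min_dist - 1e-9, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "cells %d and %d overlap beyond tolerance (centre distance %.2f um < %.2f um)",
      cells$cell_id[i], cells$cell_id[j], d[i, j], min_dist))
  }
  invisible(TRUE)
}
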