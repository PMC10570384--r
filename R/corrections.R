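#' Estimate per-channel dark current from laser-off frames
#'
#' The dark current of each PMT channel is the mean pixel value of frames
#' acquired with the acquisition settings of the experiment but the laser
#' turned off.
#'
#' @param green_frames,red_frames Laser-off frames per channel: a numeric
#'   matrix, a 3-D array of frames, or a list of matrices.
#' @return List with scalars `dark_green` and `dark_red`.
#' @export
estimate_dark_current <- function(green_frames, red_frames) {
  list(dark_green = frame_mean(green_frames, "green_frames"),
       dark_red = frame_mean(red_frames, "red_frames"))
}

frame_mean <- function(frames, what) {
  if (is.list(frames)) frames <- unlist(frames, use.names = FALSE)
  if (length(frames) == 0) stop(what, " is empty: need at least one frame")
  mean(as.numeric(frames))
}

#' Estimate the green-to-red spectral contamination ratio
#'
#' The green emission of the sensor penetrates the red detection channel.
#' Before photoconversion no converted (truly red) protein exists, so any
#' red signal covarying with green across cells is spectral leak. The
#' contamination ratio rho is the ordinary-least-squares slope of
#' dark-corrected red on dark-corrected green across pre-photoconversion
#' cells; the fitted intercept is the red autofluorescence estimate for the
#' pooled data.
#'
#' @param green,red Per-cell mean raw intensities from pre-photoconversion
#'   acquisitions (equal length, >= 3 cells).
#' @param dark_green,dark_red Dark currents to subtract first (default 0).
#' @return List with `rho`, `intercept`, `clamped` (TRUE if a negative
#'   fitted slope was clamped to 0), and the `fit` (an `lm` object).
#' @export
estimate_contamination_ratio <- function(green, red, dark_green = 0,
                                         dark_red = 0) {
  stopifnot(length(green) == length(red))
  if (length(green) < 3) stop("need at least 3 pre-PC cells")
  g <- green - dark_green
  r <- red - dark_red
  if (stats::sd(g) == 0) stop("degenerate green values: no variance to regress on")
  fit <- stats::lm(r ~ g)
  rho <- unname(stats::coef(fit)[2])
  clamped <- FALSE
  if (rho < 0) {
    warning("fitted contamination slope is negative; clamping rho to 0")
    rho <- 0
    clamped <- TRUE
  }
  list(rho = rho, intercept = unname(stats::coef(fit)[1]),
       clamped = clamped, fit = fit)
}

#' Estimate the per-hemisphere red autofluorescence intercept
#'
#' Cranial windows sit at different angles relative to the optical axis, so
#' each hemisphere contributes its own weak red-channel autofluorescence
#' baseline. Per hemisphere, beta is the intercept of the linear regression
#' of dark-corrected red on dark-corrected green across that hemisphere's
#' pre-photoconversion cells; hemispheres are fitted independently.
#'
#' @inheritParams estimate_contamination_ratio
#' @param hemisphere Character/factor vector of hemisphere labels per cell.
#' @param rho Optional known contamination ratio; when supplied, beta is the
#'   mean residual offset `mean(red - rho * green)` per hemisphere (the
#'   intercept of the fixed-slope line) instead of a free-slope intercept.
#' @return Named numeric vector of beta per hemisphere, with attribute
#'   `flagged` naming hemispheres that had < 3 cells (their beta is 0).
#' @export
estimate_autofluorescence_intercept <- function(green, red, hemisphere,
                                                dark_green = 0, dark_red = 0,
                                                rho = NULL) {
  stopifnot(length(green) == length(red), length(green) == length(hemisphere))
  g <- green - dark_green
  r <- red - dark_red
  hemis <- sort(unique(as.character(hemisphere)))
  beta <- stats::setNames(numeric(length(hemis)), hemis)
  flagged <- character(0)
  for (h in hemis) {
    sel <- hemisphere == h
    if (sum(sel) < 3) {
      warning("hemisphere ", h, " has fewer than 3 pre-PC cells; beta set to 0")
      flagged <- c(flagged, h)
      next
    }
    beta[h] <- if (is.null(rho)) {
      unname(stats::coef(stats::lm(r[sel] ~ g[sel]))[1])
    } else {
      mean(r[sel] - rho * g[sel])
    }
  }
  attr(beta, "flagged") <- flagged
  beta
}

#' Estimate the full correction parameter set from pre-PC cells
#'
#' Joint estimation of the spectral contamination ratio and per-hemisphere
#' autofluorescence intercepts from one regression: dark-corrected red on
#' dark-corrected green with a common slope (the physics of spectral leak
#' does not depend on the window) and a separate intercept per hemisphere.
#' Setting `per_hemisphere_rho = TRUE` instead fits slope and intercept
#' independently per hemisphere. Cells with studentized residual > 4 are
#' reported as outliers but not removed.
#'
#' @inheritParams estimate_autofluorescence_intercept
#' @param per_hemisphere_rho Fit a separate contamination slope per
#'   hemisphere (default FALSE).
#' @return Object of class `campari_corrections`: list with `dark_green`,
#'   `dark_red`, `rho` (scalar, or named per hemisphere), `beta` (named per
#'   hemisphere), `clamped`, `outliers` (data.frame of flagged cells), and
#'   fit diagnostics (`sigma`, `n`).
#' @export
estimate_corrections <- function(green, red, hemisphere,
                                 dark_green = 0, dark_red = 0,
                                 per_hemisphere_rho = FALSE) {
  stopifnot(length(green) == length(red), length(green) == length(hemisphere))
  if (length(green) < 3) stop("need at least 3 pre-PC cells")
  g <- green - dark_green
  r <- red - dark_red
  hemi <- factor(as.character(hemisphere))
  if (stats::sd(g) == 0) stop("degenerate green values: no variance to regress on")

  if (per_hemisphere_rho) {
    rho <- stats::setNames(numeric(nlevels(hemi)), levels(hemi))
    beta <- rho
    resid_st <- rep(NA_real_, length(g))
    sig <- NA_real_
    for (h in levels(hemi)) {
      sel <- hemi == h
      if (sum(sel) < 3) stop("hemisphere ", h, " has fewer than 3 cells")
      fit <- stats::lm(r[sel] ~ g[sel])
      rho[h] <- unname(stats::coef(fit)[2])
      beta[h] <- unname(stats::coef(fit)[1])
      resid_st[sel] <- stats::rstudent(fit)
    }
  } else if (nlevels(hemi) > 1) {
    fit <- stats::lm(r ~ g + hemi)
    cf <- stats::coef(fit)
    rho <- unname(cf["g"])
    beta <- stats::setNames(numeric(nlevels(hemi)), levels(hemi))
    beta[1] <- cf[1]
    for (h in levels(hemi)[-1]) beta[h] <- cf[1] + cf[paste0("hemi", h)]
    resid_st <- stats::rstudent(fit)
    sig <- stats::sigma(fit)
  } else {
    fit <- stats::lm(r ~ g)
    rho <- unname(stats::coef(fit)[2])
    beta <- stats::setNames(stats::coef(fit)[1], levels(hemi))
    resid_st <- stats::rstudent(fit)
    sig <- stats::sigma(fit)
  }

  clamped <- FALSE
  if (any(rho < 0)) {
    warning("fitted contamination slope is negative; clamping rho to 0")
    rho[rho < 0] <- 0
    clamped <- TRUE
  }
  # an (almost) exact fit has no meaningful studentized residuals
  if (!per_hemisphere_rho && is.finite(sig) && sig < 1e-8)
    resid_st <- rep(NA_real_, length(g))
  out_idx <- which(!is.na(resid_st) & abs(resid_st) > 4)
  outliers <- data.frame(index = out_idx, studentized_residual = resid_st[out_idx])
  structure(list(dark_green = dark_green, dark_red = dark_red,
                 rho = rho, beta = beta, clamped = clamped,
                 outliers = outliers,
                 sigma = if (per_hemisphere_rho) NA_real_ else sig,
                 n = length(g)),
            class = "campari_corrections")
}

#' @export
print.campari_corrections <- function(x, ...) {
  cat("campari_corrections\n")
  cat(sprintf("  dark current: green %.4g, red %.4g\n", x$dark_green, x$dark_red))
  cat("  contamination ratio rho:",
      paste(sprintf("%.4g", x$rho), collapse = ", "), "\n")
  cat("  autofluorescence beta:",
      paste(sprintf("%s=%.4g", names(x$beta), x$beta), collapse = ", "), "\n")
  if (nrow(x$outliers))
    cat("  outlier cells (|studentized residual| > 4):",
        paste(x$outliers$index, collapse = ", "), "\n")
  invisible(x)
}

#' Apply channel corrections to raw per-cell intensities
#'
#' Applies the corrections in the fixed order: dark-current subtraction per
#' channel, then subtraction of the hemisphere's autofluorescence offset and
#' of the contamination leak from the red channel:
#' `g_corr = g - dark_green`;
#' `r_corr = r - dark_red - beta(hemisphere) - rho * g_corr`.
#' Cells whose corrected green is not positive cannot yield a stable ratio
#' and are flagged as failing QC (they are excluded downstream and counted,
#' not clipped).
#'
#' @param green,red Raw per-cell mean intensities.
#' @param params A `campari_corrections` object (or compatible list with
#'   fields dark_green, dark_red, rho, beta).
#' @param hemisphere Hemisphere label(s) of the cells (scalar or vector).
#' @return data.frame with columns `g_corr`, `r_corr`, `qc_pass`.
#' @export
apply_corrections <- function(green, red, params, hemisphere) {
  stopifnot(length(green) == length(red))
  hemisphere <- rep_len(as.character(hemisphere), length(green))
  beta <- hemisphere_beta(params$beta, hemisphere)
  rho <- params$rho
  if (!is.null(names(rho)) && length(rho) > 1) {
    rho <- rho[hemisphere]
    if (anyNA(rho)) stop("no contamination ratio for some hemisphere(s)")
    rho <- unname(rho)
  }
  g_corr <- green - params$dark_green
  r_corr <- red - params$dark_red - beta - rho * g_corr
  data.frame(g_corr = g_corr, r_corr = r_corr, qc_pass = g_corr > 0)
}
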