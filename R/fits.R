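#' Fit an exponential decay to normalized RGR time courses
#'
#' Nonlinear least-squares fit of `y = A * 2^(-t / t_half) + C` to (day,
#' value) data, typically the across-cell medians of a normalized decay
#' cohort. Because traces are normalized to their value immediately after
#' photoconversion, the default fixes the amplitude A at 1 and the offset C
#' at 0; both can be freed. Reports the half-life with its standard error
#' and R-squared relative to the constant-mean model.
#'
#' @param day Numeric vector of observation days (>= 3 points, incl. day 0
#'   when `fix_amplitude = TRUE`).
#' @param value Normalized RGR at each day.
#' @param fix_amplitude Fix A = 1 (default TRUE).
#' @param fit_offset Free offset C (default FALSE).
#' @return Object of class `campari_decay_fit`: list with `half_life`,
#'   `half_life_se`, `amplitude`, `offset`, `r_squared`, `fitted` (values at
#'   the input days) and the underlying `nls` model.
#' @export
fit_decay <- function(day, value, fix_amplitude = TRUE, fit_offset = FALSE) {
  stopifnot(length(day) == length(value))
  keep <- !is.na(day) & !is.na(value)
  day <- day[keep]; value <- value[keep]
  if (length(day) < 3) stop("need at least 3 time points")
  if (all(diff(value[order(day)]) >= 0))
    warning("values are non-decreasing in time; decay fit may be meaningless")

  # starting half-life from the log-linear slope of the positive values
  pos <- value > 0
  t0 <- if (sum(pos) >= 2 && stats::sd(day[pos]) > 0) {
    sl <- stats::coef(stats::lm(log2(value[pos]) ~ day[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else 1
  } else 1
  start <- list(thalf = max(t0, 1e-3))
  df <- data.frame(t = day, y = value)

  form <- if (fix_amplitude && !fit_offset) {
    y ~ 2^(-t / thalf)
  } else if (fix_amplitude && fit_offset) {
    start$C <- min(value)
    y ~ (1 - C) * 2^(-t / thalf) + C
  } else if (!fix_amplitude && !fit_offset) {
    start$A <- max(value)
    y ~ A * 2^(-t / thalf)
  } else {
    start$A <- max(value) - min(value); start$C <- min(value)
    y ~ A * 2^(-t / thalf) + C
  }
  fit <- minpack.lm::nlsLM(form, data = df, start = start,
                           lower = c(thalf = 1e-6,
                                     if (!fix_amplitude) c(A = 0),
                                     if (fit_offset) c(C = -Inf)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["thalf"],
                 error = function(e) NA_real_)
  fitted_vals <- stats::predict(fit)
  ss_res <- sum((value - fitted_vals)^2)
  ss_tot <- sum((value - mean(value))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(half_life = unname(cf["thalf"]),
                 half_life_se = unname(se),
                 amplitude = if ("A" %in% names(cf)) unname(cf["A"]) else 1,
                 offset = if ("C" %in% names(cf)) unname(cf["C"]) else 0,
                 r_squared = r2, fitted = fitted_vals, model = fit,
                 day = day, value = value),
            class = "campari_decay_fit")
}

#' @export
print.campari_decay_fit <- function(x, ...) {
  cat(sprintf("exponential decay fit: t1/2 = %.4g +/- %.2g days, R^2 = %.4g\n",
              x$half_life, x$half_life_se, x$r_squared))
  invisible(x)
}

#' Predict the decay model at given times
#'
#' @param object A `campari_decay_fit`.
#' @param t Days at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Fitted normalized RGR at `t`.
#' @export
predict.campari_decay_fit <- function(object, t, ...) {
  object$amplitude * 2^(-t / object$half_life) + object$offset
}

#' Fractional RGR loss predicted at a given day
#'
#' Convenience wrapper: `1 - predict(fit, t) / predict(fit, 0)`.
#'
#' @param fit A `campari_decay_fit`.
#' @param t Day (>= 0).
#' @return Fractional loss in \[0, 1\].
#' @export
decay_loss <- function(fit, t) {
  1 - predict(fit, t) / predict(fit, 0)
}

#' Polynomial dose-response fit with located maximum
#'
#' Least-squares polynomial fit of a response (e.g. d' or a normalized
#' fluorescence level) against light dose, as used to characterize the
#' dose-response of population separation (3rd order), green loss (1st
#' order) and red gain (2nd order). The location of the fitted maximum is
#' found by evaluating the polynomial on a dose grid over the observed
#' range.
#'
#' @param dose Numeric vector of doses.
#' @param y Response at each dose.
#' @param degree Polynomial degree (>= 1); needs at least `degree + 1`
#'   distinct doses.
#' @param grid_spacing Spacing of the evaluation grid in dose units
#'   (default 1).
#' @return List with `coefficients` (intercept first), `fitted_max_dose`,
#'   `fitted_max_value`, `r_squared`, `model` (lm), `grid` (data.frame of
#'   dose/fitted value).
#' @export
fit_dose_response <- function(dose, y, degree = 3, grid_spacing = 1) {
  stopifnot(length(dose) == length(y), degree >= 1)
  if (length(unique(dose)) < degree + 1)
    stop("need at least degree + 1 distinct doses (rank deficiency)")
  fit <- stats::lm(y ~ poly(dose, degree, raw = TRUE))
  if (fit$rank < degree + 1) stop("rank-deficient polynomial fit")
  grid <- seq(min(dose), max(dose), by = grid_spacing)
  if (grid[length(grid)] < max(dose)) grid <- c(grid, max(dose))
  gy <- stats::predict(fit, newdata = data.frame(dose = grid))
  imax <- which.max(gy)
  # suppress the "essentially perfect fit" note on exact polynomial data
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(coefficients = unname(stats::coef(fit)),
       fitted_max_dose = grid[imax], fitted_max_value = gy[imax],
       r_squared = r2, model = fit,
       grid = data.frame(dose = grid, fitted = gy))
}

#' Integrate stimulus-evoked calcium responses
#'
#' For each appearance of the drifting grating, sums the fluorescence over
#' the response window (the grating presentation) divided by 2, minus the
#' summed fluorescence over the 2-s baseline window immediately before the
#' grating: `sum(F_resp / 2) - sum(F_base)`. The response window is twice
#' the baseline window, so a constant trace integrates to exactly zero. The
#' per-appearance values are summed over all grating appearances. An
#' appearance without a full baseline window (e.g. a grating starting at the
#' first frame) is skipped with a warning.
#'
#' @param trace Numeric fluorescence trace (one cell).
#' @param epochs data.frame with 1-based `onset`/`offset` frames per grating
#'   appearance (e.g. from [simulate_grating_traces()]).
#' @param frame_rate Frames per second of the trace.
#' @param baseline_duration Baseline window length in seconds (default 2).
#' @return List with `total` (summed integrated response), `per_epoch`
#'   (data.frame `epoch`, `value`, `skipped`), `n_used`.
#' @export
integrate_grating_response <- function(trace, epochs, frame_rate,
                                       baseline_duration = 2) {
  stopifnot(is.numeric(trace), frame_rate > 0, baseline_duration > 0,
            all(epochs$onset >= 1), all(epochs$offset <= length(trace)),
            all(epochs$onset <= epochs$offset))
  base_n <- round(baseline_duration * frame_rate)
  n <- nrow(epochs)
  value <- rep(NA_real_, n)
  skipped <- logical(n)
  for (e in seq_len(n)) {
    on <- epochs$onset[e]; off <- epochs$offset[e]
    if (on - base_n < 1) {
      skipped[e] <- TRUE
      next
    }
    f_resp <- trace[on:off]
    f_base <- trace[(on - base_n):(on - 1)]
    value[e] <- sum(f_resp / 2) - sum(f_base)
  }
  if (any(skipped))
    warning(sum(skipped),
            " grating appearance(s) lacked a full baseline window; skipped")
  list(total = sum(value, na.rm = TRUE),
       per_epoch = data.frame(epoch = seq_len(n), value = value,
                              skipped = skipped),
       n_used = sum(!skipped))
}
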