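#' Simulate a longitudinal RGR decay cohort
#'
#' Generates per-cell normalized red-to-green ratio (RGR) time courses after
#' a single photoconversion event. Each cell's trace is normalized to its
#' value immediately after photoconversion, so day 0 is exactly 1; the
#' expected value at day t is `2^(-t / half_life)`. Later days carry
#' multiplicative log-normal noise with median 1 and coefficient of
#' variation `noise_cv`, so the across-cell median at each day remains on
#' the exponential.
#'
#' @param n_cells Number of cells in the cohort (default 73, a typical
#'   two-mouse longitudinal sample).
#' @param days Observation days; must be non-negative and include day 0.
#' @param half_life Decay half-life in days (> 0); default 1.04.
#' @param noise_cv Coefficient of variation of the per-observation
#'   multiplicative noise; default 0.2.
#' @param seed Optional integer seed.
#' @return data.frame with columns `cell_id`, `day`, `rgr_norm`.
#' @export
simulate_decay_cohort <- function(n_cells = 73,
                                  days = c(0, 1, 2, 3, 5, 7, 10, 15),
                                  half_life = 1.04, noise_cv = 0.2,
                                  seed = NULL) {
  if (half_life <= 0) stop("half_life must be > 0")
  stopifnot(n_cells >= 1, all(days >= 0), noise_cv >= 0)
  if (!any(days == 0)) stop("days must include day 0 (the normalization point)")
  if (!is.null(seed)) set.seed(seed)
  days <- sort(unique(days))
  grid <- expand.grid(cell_id = seq_len(n_cells), day = days,
                      KEEP.OUT.ATTRS = FALSE)
  expected <- 2^(-grid$day / half_life)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- stats::rlnorm(nrow(grid), meanlog = 0, sdlog = sdlog)
  noise[grid$day == 0] <- 1  # day 0 defines the normalization
  grid$rgr_norm <- expected * noise
  grid[order(grid$cell_id, grid$day), ]
}

#' Drifting-grating stimulus protocol
#'
#' Timing parameters of the visual stimulation protocol: a grating drifting
#' in one of `n_directions` directions for `grating_duration` seconds,
#' followed by `gray_duration` seconds of gray display, the full direction
#' set repeated `n_repeats` times. Defaults are the CaMPARI photoconversion
#' protocol (4 s grating / 8 s gray, 8 directions, 5 repeats at 15
#' frames/s); `jgcamp_protocol()` gives the dynamic-indicator comparator
#' protocol (4 s / 4 s at 30 frames/s).
#'
#' @param frame_rate Acquisition frame rate in frames/s.
#' @param grating_duration,gray_duration Durations in seconds (> 0).
#' @param n_directions,n_repeats Counts (>= 1).
#' @return An object of class `campari_protocol`.
#' @export
stimulus_protocol <- function(frame_rate = 15, grating_duration = 4,
                              gray_duration = 8, n_directions = 8,
                              n_repeats = 5) {
  stopifnot(frame_rate > 0, grating_duration > 0, gray_duration > 0,
            n_directions >= 1, n_repeats >= 1)
  structure(list(frame_rate = frame_rate,
                 grating_duration = grating_duration,
                 gray_duration = gray_duration,
                 n_directions = n_directions, n_repeats = n_repeats),
            class = "campari_protocol")
}

#' @rdname stimulus_protocol
#' @export
jgcamp_protocol <- function(frame_rate = 30, grating_duration = 4,
                            gray_duration = 4, n_directions = 8,
                            n_repeats = 5) {
  stimulus_protocol(frame_rate, grating_duration, gray_duration,
                    n_directions, n_repeats)
}

#' Simulate stimulus-locked calcium fluorescence traces
#'
#' Generates one fluorescence trace per requested cell under a drifting
#' grating protocol: baseline fluorescence plus a boxcar response of the
#' cell's amplitude during every grating presentation, plus Gaussian noise.
#' The accompanying epoch table marks each grating appearance with 1-based
#' onset/offset frames.
#'
#' @param protocol A [stimulus_protocol()].
#' @param response_amplitude Numeric vector: response amplitude of each
#'   simulated cell (one trace per element).
#' @param baseline Baseline fluorescence level (counts).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Optional integer seed.
#' @return List with `traces` (matrix, cells x frames), `epochs`
#'   (data.frame `epoch`, `onset`, `offset`), `frame_rate`.
#' @export
simulate_grating_traces <- function(protocol = stimulus_protocol(),
                                    response_amplitude = 20,
                                    baseline = 100, noise_sd = 2,
                                    seed = NULL) {
  stopifnot(inherits(protocol, "campari_protocol"), baseline >= 0,
            noise_sd >= 0, all(response_amplitude >= 0))
  if (!is.null(seed)) set.seed(seed)
  fr <- protocol$frame_rate
  grating_frames <- round(protocol$grating_duration * fr)
  gray_frames <- round(protocol$gray_duration * fr)
  cycle <- grating_frames + gray_frames
  n_epochs <- protocol$n_directions * protocol$n_repeats
  n_frames <- n_epochs * cycle

  onset <- (seq_len(n_epochs) - 1L) * cycle + 1L
  epochs <- data.frame(epoch = seq_len(n_epochs), onset = onset,
                       offset = onset + grating_frames - 1L)
  stim <- rep(0, n_frames)
  for (e in seq_len(n_epochs)) stim[epochs$onset[e]:epochs$offset[e]] <- 1

  n_cells <- length(response_amplitude)
  traces <- matrix(baseline, n_cells, n_frames) +
    outer(response_amplitude, stim)
  if (noise_sd > 0)
    traces <- traces + matrix(stats::rnorm(n_cells * n_frames, 0, noise_sd),
                              n_cells, n_frames)
  list(traces = traces, epochs = epochs, frame_rate = fr)
}
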