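#' Configure the synthetic dynamic-MR thermometry phantom
#'
#' Builds the parameter set for [generate_series()]. Defaults emulate the
#' acquisition conditions of ECG-triggered cardiac PRFS thermometry at 1.5 T:
#' one frame per heartbeat (~1 s), 0.8 mm reconstructed in-plane pixels,
#' 250 repetitions with RF energy switched on at the 50th image, free-breathing
#' respiratory rates around 24 breaths/min with a few millimetres of residual
#' in-plane displacement, susceptibility phase linearly coupled to the
#' respiratory displacement, a slow scanner B0 drift (about 5 degC-equivalent
#' over 150 s), and a localized heating hotspot reaching up to 75 degC above
#' baseline.
#'
#' @param grid_size integer length-2, image height and width in pixels.
#' @param pixel_spacing in-plane pixel size in mm.
#' @param frame_interval time between frames in s (one simulated heartbeat).
#' @param n_frames number of frames in the series.
#' @param resp_amplitude peak in-plane respiratory displacement in mm.
#' @param resp_rate respiratory rate in breaths/min.
#' @param susceptibility_gain peak magnitude of the susceptibility gain map in
#'   rad per mm of displacement. The default gain map is a planar gradient
#'   running across the field of view from `-susceptibility_gain` to
#'   `+susceptibility_gain`; pass `gain_map` to override it.
#' @param gain_map optional matrix (same shape as the grid) of rad/mm gains.
#' @param drift_rate spatially uniform phase drift in rad/s.
#' @param heat_peak peak temperature rise of the hotspot in degC.
#' @param heat_sigma Gaussian spatial width of the hotspot in mm.
#' @param heat_center hotspot centre as (row, col) pixel coordinates
#'   (default: grid centre).
#' @param heat_onset_frame 1-based frame index at which RF delivery starts.
#' @param heat_duration_frames number of frames of RF delivery.
#' @param heat_rise_tau,heat_decay_tau exponential time constants (s) of the
#'   heating envelope during and after RF delivery.
#' @param snr magnitude signal-to-noise ratio at nominal tissue intensity
#'   (use `Inf` for a noise-free series).
#' @param te,b0,gamma_over_2pi,alpha_ppm PRFS acquisition constants used to
#'   write the heating phase with the same convention as the thermometry
#'   stage (see [prfs_params()]).
#' @param seed integer seed controlling the noise realization.
#'
#' @return An object of class `phantom_config`.
#' @seealso [generate_series()], [true_dose()]
#' @export
phantom_config <- function(grid_size = c(96L, 96L),
                           pixel_spacing = 0.8,
                           frame_interval = 1.0,
                           n_frames = 250L,
                           resp_amplitude = 5,
                           resp_rate = 24,
                           susceptibility_gain = 0.05,
                           gain_map = NULL,
                           drift_rate = 0.0023,
                           heat_peak = 75,
                           heat_sigma = 2.5,
                           heat_center = NULL,
                           heat_onset_frame = 50L,
                           heat_duration_frames = 40L,
                           heat_rise_tau = 15,
                           heat_decay_tau = 30,
                           snr = 80,
                           te = 0.018,
                           b0 = 1.5,
                           gamma_over_2pi = 42.58e6,
                           alpha_ppm = -0.0094,
                           seed = 1L) {
  if (length(grid_size) != 2 || any(grid_size < 8)) {
    stop("'grid_size' must be two integers >= 8", call. = FALSE)
  }
  check_positive(pixel_spacing, "pixel_spacing")
  check_positive(frame_interval, "frame_interval")
  check_positive(n_frames, "n_frames")
  check_positive(resp_amplitude, "resp_amplitude", strict = FALSE)
  check_positive(resp_rate, "resp_rate", strict = FALSE)
  check_positive(susceptibility_gain, "susceptibility_gain", strict = FALSE)
  if (!is.finite(drift_rate)) stop("'drift_rate' must be finite", call. = FALSE)
  check_positive(heat_peak, "heat_peak", strict = FALSE)
  check_positive(heat_sigma, "heat_sigma")
  check_positive(heat_onset_frame, "heat_onset_frame")
  check_positive(heat_duration_frames, "heat_duration_frames", strict = FALSE)
  check_positive(heat_rise_tau, "heat_rise_tau")
  check_positive(heat_decay_tau, "heat_decay_tau")
  if (!(is.numeric(snr) && length(snr) == 1 && (is.infinite(snr) || snr > 0))) {
    stop("'snr' must be > 0 (or Inf for noise-free)", call. = FALSE)
  }
  if (n_frames < heat_onset_frame + 1) {
    stop("'n_frames' must be >= heat_onset_frame + 1", call. = FALSE)
  }
  if (is.null(heat_center)) heat_center <- (grid_size + 1) / 2
  if (!is.null(gain_map) && !identical(dim(gain_map), as.integer(grid_size))) {
    stop("'gain_map' must match grid_size", call. = FALSE)
  }
  structure(list(
    grid_size = as.integer(grid_size), pixel_spacing = pixel_spacing,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    resp_amplitude = resp_amplitude, resp_rate = resp_rate,
    susceptibility_gain = susceptibility_gain, gain_map = gain_map,
    drift_rate = drift_rate, heat_peak = heat_peak, heat_sigma = heat_sigma,
    heat_center = heat_center, heat_onset_frame = as.integer(heat_onset_frame),
    heat_duration_frames = as.integer(heat_duration_frames),
    heat_rise_tau = heat_rise_tau, heat_decay_tau = heat_decay_tau,
    snr = snr, prfs = prfs_params(te = te, b0 = b0,
                                  gamma_over_2pi = gamma_over_2pi,
                                  alpha_ppm = alpha_ppm),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Physical (mm) coordinate grids, centred on the image.
phantom_grid_mm <- function(config) {
  h <- config$grid_size[1]; w <- config$grid_size[2]; sp <- config$pixel_spacing
  y <- (seq_len(h) - (h + 1) / 2) * sp
  x <- (seq_len(w) - (w + 1) / 2) * sp
  list(y = matrix(y, h, w), x = matrix(x, h, w, byrow = TRUE))
}

#' Noiseless anatomy magnitude template of the phantom
#'
#' The template is an analytic function of physical coordinates: a large soft-
#' edged tissue disc at nominal intensity 1 carrying a smooth sinusoidal
#' texture (so the optical-flow stage has intensity gradients to work with)
#' over a dim background. Being analytic, the template can be evaluated at
#' displaced coordinates, which makes the phantom's motion warping exact.
#'
#' @param config a [phantom_config()].
#' @param shift_mm length-2 numeric, (y, x) displacement of the anatomy in mm.
#' @return Magnitude matrix of size `grid_size`.
#' @export
phantom_template <- function(config, shift_mm = c(0, 0)) {
  g <- phantom_grid_mm(config)
  y <- g$y - shift_mm[1]; x <- g$x - shift_mm[2]
  fov <- min(config$grid_size) * config$pixel_spacing
  r <- sqrt(x^2 + y^2)
  body <- 1 / (1 + exp((r - 0.42 * fov) / 2))
  0.05 + body * (0.95 + 0.15 * sin(2 * pi * x / 12) * cos(2 * pi * y / 12))
}

# Smooth anatomy phase template (rad), also analytic in mm coordinates.
phantom_phase_template <- function(config, shift_mm = c(0, 0)) {
  g <- phantom_grid_mm(config)
  y <- g$y - shift_mm[1]; x <- g$x - shift_mm[2]
  0.4 * sin(2 * pi * x / 40) + 0.3 * cos(2 * pi * y / 33)
}

# Respiratory in-plane displacement (mm) at each frame time; motion is along
# the row (head-foot) axis. Ranges 0..resp_amplitude, breathing-like.
phantom_displacement <- function(config) {
  t <- (seq_len(config$n_frames) - 1) * config$frame_interval
  f <- config$resp_rate / 60
  config$resp_amplitude * (1 - cos(2 * pi * f * t)) / 2
}

# Heating envelope (0..1) at each frame time.
phantom_envelope <- function(config) {
  t <- (seq_len(config$n_frames) - 1) * config$frame_interval
  t_on <- (config$heat_onset_frame - 1) * config$frame_interval
  t_off <- t_on + config$heat_duration_frames * config$frame_interval
  env <- numeric(config$n_frames)
  on <- t >= t_on & t < t_off
  env[on] <- 1 - exp(-(t[on] - t_on) / config$heat_rise_tau)
  peak <- 1 - exp(-(t_off - t_on) / config$heat_rise_tau)
  post <- t >= t_off
  env[post] <- peak * exp(-(t[post] - t_off) / config$heat_decay_tau)
  env
}

phantom_gain_map <- function(config) {
  if (!is.null(config$gain_map)) return(config$gain_map)
  g <- phantom_grid_mm(config)
  half_fov <- max(abs(g$x))
  config$susceptibility_gain * g$x / half_fov
}

#' Generate a synthetic dynamic MR thermometry series with ground truth
#'
#' Simulates a 2D+t complex MR acquisition: a smooth anatomy template warped
#' by periodic in-plane respiratory motion, with per-frame phase composed of
#' the (co-moving) anatomy phase, a heating phase written with the PRFS
#' constant of the thermometry stage (sign-consistent, so heating lowers the
#' phase), a susceptibility phase linear in the respiratory displacement, a
#' spatially uniform drift, and complex Gaussian noise (Rician magnitude).
#'
#' @param config a [phantom_config()].
#' @return A list with elements
#'   \describe{
#'     \item{series}{a `frame_series`: `magnitude` and `phase` arrays of size
#'       H x W x n_frames, `times` (s), `pixel_spacing` (mm).}
#'     \item{truth}{ground truth: `dT` (H x W x n_frames, degC, in reference
#'       coordinates), `motion` (n_frames x 2 matrix of (dy, dx) pixel
#'       translations), `displacement_mm`, `gain_map` (rad/mm),
#'       `drift` (rad per frame), `envelope`, `template` (noiseless
#'       magnitude), `k` (degC/rad).}
#'   }
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$grid_size[1]; w <- config$grid_size[2]; n <- config$n_frames
  times <- (seq_len(n) - 1) * config$frame_interval
  disp <- phantom_displacement(config)
  env <- phantom_envelope(config)
  gain <- phantom_gain_map(config)
  k <- prfs_constant(config$prfs)
  g <- phantom_grid_mm(config)
  cy <- (config$heat_center[1] - (h + 1) / 2) * config$pixel_spacing
  cx <- (config$heat_center[2] - (w + 1) / 2) * config$pixel_spacing
  hot_ref <- exp(-((g$y - cy)^2 + (g$x - cx)^2) / (2 * config$heat_sigma^2))

  magnitude <- array(0, c(h, w, n))
  phase <- array(0, c(h, w, n))
  dT_true <- array(0, c(h, w, n))
  drift <- config$drift_rate * times
  sigma_noise <- if (is.infinite(config$snr)) 0 else 1 / config$snr

  set.seed(config$seed)
  for (i in seq_len(n)) {
    shift <- c(disp[i], 0) # (y, x) mm: head-foot axis
    A <- phantom_template(config, shift)
    phi_anat <- phantom_phase_template(config, shift)
    # heating rides with the tissue: evaluate the hotspot at displaced coords
    hot_i <- exp(-((g$y - shift[1] - cy)^2 + (g$x - shift[2] - cx)^2) /
                   (2 * config$heat_sigma^2))
    dT_i <- config$heat_peak * env[i] * hot_i
    phi <- phi_anat + dT_i / k + gain * disp[i] + drift[i]
    z <- A * exp(1i * phi)
    if (sigma_noise > 0) {
      z <- z + complex(real = rnorm(h * w, 0, sigma_noise),
                       imaginary = rnorm(h * w, 0, sigma_noise))
    }
    magnitude[, , i] <- Mod(z)
    phase[, , i] <- Arg(z)
    dT_true[, , i] <- config$heat_peak * env[i] * hot_ref
  }

  series <- structure(list(
    magnitude = magnitude, phase = phase, times = times,
    pixel_spacing = config$pixel_spacing
  ), class = "frame_series")
  truth <- list(
    dT = dT_true,
    motion = cbind(dy = disp / config$pixel_spacing, dx = rep(0, n)),
    displacement_mm = disp, gain_map = gain, drift = drift,
    envelope = env, template = phantom_template(config), k = k,
    hot_ref = hot_ref
  )
  list(series = series, truth = truth)
}

#' Dense-integration thermal dose on the phantom ground truth
#'
#' Brute-force reference for the streaming dose integrator: the CEM43
#' integrand is evaluated on the true temperature curve, linearly interpolated
#' between frames at `fine_substeps` sub-intervals per frame, and accumulated
#' with the rectangle rule. With `fine_substeps = 1` this reproduces the
#' causal per-frame integrator exactly; large values give a converged dense
#' integral.
#'
#' @param truth ground truth as returned by [generate_series()].
#' @param t_ref reference absolute body temperature in degC (default 37).
#' @param fine_substeps sub-intervals per frame interval (>= 1).
#' @param frame_interval frame spacing in s (default 1 s).
#' @return A `thermal_dose_map` (see [dose_map()]).
#' @export
true_dose <- function(truth, t_ref = 37, fine_substeps = 1L,
                      frame_interval = 1.0) {
  check_positive(fine_substeps, "fine_substeps")
  dims <- dim(truth$dT)
  n <- dims[3]
  dose <- dose_map(dims[1:2])
  m <- as.integer(fine_substeps)
  for (i in seq_len(n)) {
    T0 <- t_ref + truth$dT[, , i]
    T1 <- if (i < n) t_ref + truth$dT[, , i + 1] else T0
    for (s in seq_len(m)) {
      f <- (s - 1) / m
      dose <- dose_step(dose, T0 + f * (T1 - T0), frame_interval / m)
    }
  }
  dose
}
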