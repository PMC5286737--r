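#' Configure the thermometry/dosimetry pipeline
#'
#' @param te,b0,gamma_over_2pi,alpha_ppm PRFS constants (see [prfs_params()]).
#' @param n_learn learning frames for the susceptibility flow model
#'   (default 30, the first repetitions of the series).
#' @param sigma_baseline_window pre-RF frames over which the dose-correction
#'   uncertainty map sigma_T is computed (default 20).
#' @param rf_start_frame 1-based frame at which RF delivery starts
#'   (default 50). Must satisfy
#'   `n_learn + sigma_baseline_window <= rf_start_frame`.
#' @param cutoff_hz,filter_order causal Butterworth temporal filter on the
#'   temperature maps (defaults 0.14 Hz, order 2).
#' @param n_basis motion-basis components retained (default 2).
#' @param flow_smoothness,flow_iters optical-flow parameters (see
#'   [estimate_flow()]).
#' @param exclusion_threshold stability exclusion threshold in degC
#'   (default 7).
#' @param t_ref reference absolute body temperature in degC (rectal
#'   temperature in practice; default 37).
#' @param lethal_threshold lethal dose threshold in normalized units
#'   (default 1 = 240 equivalent minutes at 43 degC).
#' @param pixel_spacing in-plane pixel size in mm (default 0.8).
#' @param hotspot optional (row, col) of the expected heating focus (catheter
#'   tip); used to seed the lesion extraction and to exclude the heated
#'   region from drift estimation.
#' @param drift_mask optional logical matrix of drift-stable pixels; when
#'   `NULL`, all pixels farther than `drift_exclude_radius_mm` from `hotspot`
#'   (or all pixels if no hotspot is given — the median is robust to a small
#'   heated region).
#' @param drift_exclude_radius_mm radius around the hotspot excluded from
#'   drift estimation (default 10 mm, about four hotspot widths).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(te = 0.018, b0 = 1.5, gamma_over_2pi = 42.58e6,
                            alpha_ppm = -0.0094,
                            n_learn = 30L, sigma_baseline_window = 20L,
                            rf_start_frame = 50L,
                            cutoff_hz = 0.14, filter_order = 2L,
                            n_basis = 2L, flow_smoothness = 0.2,
                            flow_iters = 100L,
                            exclusion_threshold = 7, t_ref = 37,
                            lethal_threshold = 1.0, pixel_spacing = 0.8,
                            hotspot = NULL, drift_mask = NULL,
                            drift_exclude_radius_mm = 10) {
  if (n_learn + sigma_baseline_window > rf_start_frame) {
    stop("n_learn + sigma_baseline_window must not exceed rf_start_frame ",
         "(learning and baseline precede heating)", call. = FALSE)
  }
  check_positive(n_learn, "n_learn")
  check_positive(sigma_baseline_window, "sigma_baseline_window")
  if (sigma_baseline_window < 2) {
    stop("'sigma_baseline_window' must be >= 2 frames", call. = FALSE)
  }
  check_positive(lethal_threshold, "lethal_threshold")
  check_positive(pixel_spacing, "pixel_spacing")
  structure(list(
    prfs = prfs_params(te = te, b0 = b0, gamma_over_2pi = gamma_over_2pi,
                       alpha_ppm = alpha_ppm),
    n_learn = as.integer(n_learn),
    sigma_baseline_window = as.integer(sigma_baseline_window),
    rf_start_frame = as.integer(rf_start_frame),
    cutoff_hz = cutoff_hz, filter_order = as.integer(filter_order),
    n_basis = as.integer(n_basis), flow_smoothness = flow_smoothness,
    flow_iters = as.integer(flow_iters),
    exclusion_threshold = exclusion_threshold, t_ref = t_ref,
    lethal_threshold = lethal_threshold, pixel_spacing = pixel_spacing,
    hotspot = hotspot, drift_mask = drift_mask,
    drift_exclude_radius_mm = drift_exclude_radius_mm
  ), class = "pipeline_config")
}

default_drift_mask <- function(dim, config) {
  if (!is.null(config$drift_mask)) return(config$drift_mask)
  m <- matrix(TRUE, dim[1], dim[2])
  if (!is.null(config$hotspot)) {
    r_px <- config$drift_exclude_radius_mm / config$pixel_spacing
    d2 <- (row(m) - config$hotspot[1])^2 + (col(m) - config$hotspot[2])^2
    m <- d2 > r_px^2
  }
  m
}

#' Run the full real-time thermometry and dosimetry pipeline
#'
#' Frames are processed strictly in acquisition order with a causal
#' (streaming) contract: no output for frame t depends on any later frame.
#' Per frame: optical-flow motion estimation against the first-frame
#' reference, projection onto the learned motion basis (denoised flow),
#' phase registration, temporal unwrapping, susceptibility correction from
#' the learned flow-phase model, scalar drift correction, PRFS conversion,
#' causal temporal low-pass filtering, and CEM43 dose accumulation. The
#' motion basis and the susceptibility model are learned on the first
#' `n_learn` frames; the reference phase is the mean corrected phase over
#' frames `n_learn + 1 .. rf_start_frame - 1`; the dose-correction
#' uncertainty map is the temperature standard deviation over the
#' `sigma_baseline_window` frames immediately preceding RF. Temperature maps
#' are emitted from `rf_start_frame` onward.
#'
#' @param series a `frame_series` (from [generate_series()] or
#'   [read_series_nifti()]).
#' @param config a [pipeline_config()].
#' @return A `ctm_result` list:
#'   \describe{
#'     \item{temperature}{`dT` array (H x W x emitted frames, degC,
#'       filtered), `frames` (their 1-based indices), `mu_map`, `sigma_map`,
#'       `exclusion_mask`, `k`.}
#'     \item{dose}{`thermal_dose_map` with `sigma_baseline` and `corrected`.}
#'     \item{lesion}{one-row tibble from [lesion_dimensions()].}
#'     \item{basis, model}{the learned motion basis and susceptibility
#'       model.}
#'     \item{log}{tibble of stage messages and timings.}
#'   }
#' @export
run_pipeline <- function(series, config = pipeline_config()) {
  stopifnot(inherits(series, "frame_series"))
  stopifnot(inherits(config, "pipeline_config"))
  dims <- dim(series$magnitude)
  n <- dims[3]
  if (!identical(dim(series$phase), dims)) {
    stop("magnitude and phase series must have identical dimensions",
         call. = FALSE)
  }
  if (n <= config$rf_start_frame) {
    stop("series must extend beyond rf_start_frame", call. = FALSE)
  }
  h <- dims[1]; w <- dims[2]
  dt <- if (n > 1) series$times[2] - series$times[1] else 1
  k <- prfs_constant(config$prfs)
  log_rows <- list()
  t_start <- proc.time()[["elapsed"]]
  note <- function(stage, msg) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, message = msg,
      elapsed_s = proc.time()[["elapsed"]] - t_start)
  }

  ref_mag <- series$magnitude[, , 1]
  drift_mask <- default_drift_mask(c(h, w), config)

  flows <- vector("list", config$n_learn)
  unwrapped_learn <- array(0, c(h, w, config$n_learn))
  corrected <- array(0, c(h, w, n)) # corrected phase, frames > 0 used lazily
  prev_raw <- NULL
  prev_unwrapped <- NULL
  basis <- NULL
  model <- NULL
  coeffs_learn <- NULL
  ref_phase <- NULL
  sigma_baseline <- NULL
  filt <- butter_filter(c(h, w), config$cutoff_hz, 1 / dt,
                        config$filter_order)
  dose <- dose_map(c(h, w))
  n_emit <- n - config$rf_start_frame + 1
  dT_out <- array(0, c(h, w, n_emit))
  drifts <- numeric(n)

  for (t in seq_len(n)) {
    mag_t <- series$magnitude[, , t]
    phase_t <- series$phase[, , t]
    flow_t <- estimate_flow(mag_t, ref_mag, smoothness = config$flow_smoothness,
                            n_iter = config$flow_iters)
    if (t <= config$n_learn) {
      flows[[t]] <- flow_t
      reg <- warp(phase_t, flow_t, phase = TRUE)
      unw <- unwrap_step(prev_raw, prev_unwrapped, reg)
      unwrapped_learn[, , t] <- unw
      prev_raw <- reg; prev_unwrapped <- unw
      if (t == config$n_learn) {
        basis <- build_motion_basis(flows, config$n_basis)
        coeffs_learn <- matrix(
          unlist(lapply(flows, project_motion, basis = basis)),
          ncol = config$n_basis, byrow = TRUE)
        model <- learn_phase_model(unwrapped_learn, coeffs_learn)
        for (i in seq_len(config$n_learn)) {
          corrected[, , i] <- correct_susceptibility(
            unwrapped_learn[, , i], coeffs_learn[i, ], model)
        }
        note("learning", sprintf(
          "motion basis (%d comps, ev %s) and susceptibility model on %d frames",
          config$n_basis,
          paste(sprintf("%.2f", basis$explained_variance), collapse = "/"),
          config$n_learn))
      }
    } else {
      c_t <- project_motion(flow_t, basis)
      flow_used <- reconstruct_motion(c_t, basis)
      reg <- warp(phase_t, flow_used, phase = TRUE)
      unw <- unwrap_step(prev_raw, prev_unwrapped, reg)
      prev_raw <- reg; prev_unwrapped <- unw
      corrected[, , t] <- correct_susceptibility(unw, c_t, model)
    }

    if (t == config$rf_start_frame - 1) {
      ref_idx <- (config$n_learn + 1):(config$rf_start_frame - 1)
      ref_phase <- apply(corrected[, , ref_idx, drop = FALSE], c(1, 2), mean)
      base_idx <- (config$rf_start_frame - config$sigma_baseline_window):
        (config$rf_start_frame - 1)
      ph <- matrix(corrected[, , base_idx], h * w, length(base_idx))
      sigma_baseline <- matrix(abs(k) * sqrt(apply(ph, 1, stats::var)), h, w)
      note("baseline", sprintf(
        "reference phase from frames %d-%d; sigma_T over %d pre-RF frames (mean %.2f degC)",
        min(ref_idx), max(ref_idx), length(base_idx), mean(sigma_baseline)))
    }

    if (t >= config$rf_start_frame) {
      diff_t <- corrected[, , t] - ref_phase
      drifts[t] <- estimate_drift(diff_t, drift_mask)
      dT <- temperature_map(corrected[, , t] - drifts[t], ref_phase, k)
      st <- lowpass_step(filt, dT)
      filt <- st$state
      dT_out[, , t - config$rf_start_frame + 1] <- st$value
      dose <- dose_step(dose, config$t_ref + st$value, dt)
    }
  }

  stats <- temperature_stats(dT_out, config$exclusion_threshold)
  dose <- correct_dose(dose, sigma_baseline)
  mask <- lethal_mask(dose, config$lethal_threshold, config$hotspot)
  if (attr(mask, "n_discarded") > 0) {
    note("lesion", sprintf("%d disconnected supra-threshold component(s) discarded",
                           attr(mask, "n_discarded")))
  }
  lesion <- lesion_dimensions(mask, config$pixel_spacing)
  note("done", sprintf("%d frames processed, %d temperature maps emitted%s",
                       n, n_emit,
                       if (lesion$n_pixels == 0) "; no lesion formed" else ""))

  structure(list(
    temperature = list(dT = dT_out,
                       frames = config$rf_start_frame:n,
                       mu_map = stats$mu_map, sigma_map = stats$sigma_map,
                       exclusion_mask = stats$exclusion_mask, k = k),
    dose = dose, lesion_mask = mask, lesion = lesion,
    basis = basis, model = model, drift = drifts,
    log = do.call(rbind, log_rows), config = config
  ), class = "ctm_result")
}

#' @export
print.ctm_result <- function(x, ...) {
  nT <- dim(x$temperature$dT)[3]
  cat(sprintf("Cardiac thermometry result: %d temperature maps (frames %d-%d)\n",
              nT, min(x$temperature$frames), max(x$temperature$frames)))
  cat(sprintf("  max dT %.1f degC; peak corrected dose %.2g x lethal\n",
              max(x$temperature$dT), max(dose_normalized(x$dose))))
  if (x$lesion$n_pixels > 0) {
    cat(sprintf("  lesion: %.1f x %.1f mm (%.1f mm^2)\n",
                x$lesion$largest_mm, x$lesion$smallest_mm, x$lesion$area_mm2))
  } else {
    cat("  no lesion (no supra-threshold dose)\n")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `ctm_result`.
#' @param ... unused.
#' @method glance ctm_result
#' @export
glance.ctm_result <- function(x, ...) {
  tibble::tibble(
    n_frames_emitted = dim(x$temperature$dT)[3],
    max_dT_c = max(x$temperature$dT),
    mean_sigma_c = mean(x$temperature$sigma_map),
    frac_excluded = mean(x$temperature$exclusion_mask),
    peak_dose_normalized = max(dose_normalized(x$dose)),
    lesion_largest_mm = x$lesion$largest_mm,
    lesion_smallest_mm = x$lesion$smallest_mm,
    lesion_area_mm2 = x$lesion$area_mm2
  )
}
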