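#' Learn the respiratory susceptibility phase model
#'
#' Breathing modulates the magnetic field, so even perfectly registered phase
#' images carry a motion-dependent susceptibility phase. Over the learning
#' frames (default: the 30 first repetitions of the series) a per-pixel
#' ordinary-least-squares fit relates the unwrapped, registered phase to the
#' motion-basis coefficients of each frame. The intercept map doubles as a
#' baseline (reference-candidate) phase; the coefficient maps predict the
#' motion-dependent phase to subtract from later frames.
#'
#' @param phases H x W x n_learn array of registered, temporally unwrapped
#'   phase images (rad).
#' @param motion_coeffs n_learn x q matrix of per-frame motion coefficients.
#' @return A `susceptibility_model`: `intercept_map`, `coefficient_maps`
#'   (list of q matrices, rad per unit coefficient), `n_learn`.
#' @export
learn_phase_model <- function(phases, motion_coeffs) {
  d <- dim(phases)
  if (is.null(d) || length(d) != 3) {
    stop("'phases' must be an H x W x n_learn array", call. = FALSE)
  }
  motion_coeffs <- as.matrix(motion_coeffs)
  n <- d[3]
  q <- ncol(motion_coeffs)
  if (nrow(motion_coeffs) != n) {
    stop("one coefficient row per learning frame required", call. = FALSE)
  }
  if (n < q + 2) {
    stop("need at least q + 2 learning frames", call. = FALSE)
  }
  Y <- t(matrix(phases, d[1] * d[2], n)) # n x HW
  X <- cbind(1, motion_coeffs)
  if (qr(X)$rank < ncol(X)) {
    warning("rank-deficient motion coefficients: intercept-only model")
    B <- rbind(colMeans(Y), matrix(0, q, ncol(Y)))
  } else {
    B <- solve(crossprod(X), crossprod(X, Y))
  }
  structure(list(
    intercept_map = matrix(B[1, ], d[1], d[2]),
    coefficient_maps = lapply(seq_len(q),
                              function(j) matrix(B[j + 1, ], d[1], d[2])),
    n_learn = n
  ), class = "susceptibility_model")
}

#' Remove the predicted motion-dependent phase from a frame
#'
#' Subtracts `sum(coefficient_maps[[j]] * coeffs[j])`, leaving the intercept
#' (baseline phase) untouched. The correction is linear and therefore not
#' idempotent: applying it twice with the same coefficients subtracts the
#' prediction twice.
#'
#' @param phase unwrapped registered phase frame (rad).
#' @param coeffs motion coefficients of this frame (length q).
#' @param model a `susceptibility_model` from [learn_phase_model()].
#' @return Corrected phase frame with attribute `"susceptibility_corrected"`
#'   set to `TRUE` (a guard against double application).
#' @export
correct_susceptibility <- function(phase, coeffs, model) {
  stopifnot(inherits(model, "susceptibility_model"))
  if (length(coeffs) != length(model$coefficient_maps)) {
    stop("coefficient count does not match the model", call. = FALSE)
  }
  if (isTRUE(attr(phase, "susceptibility_corrected"))) {
    warning("phase already susceptibility-corrected; applying again")
  }
  out <- phase
  for (j in seq_along(coeffs)) {
    out <- out - coeffs[j] * model$coefficient_maps[[j]]
  }
  attr(out, "susceptibility_corrected") <- TRUE
  out
}

#' Estimate the spatially uniform phase drift of a frame
#'
#' Gradient and shim heating during long EPI runs drifts the field slowly,
#' which masquerades as a global temperature offset (up to about 5 degC over
#' 2-3 min if uncorrected). The drift is estimated as the median phase
#' difference over a stable mask that excludes the heated region, and is
#' subtracted frame-wide before temperature conversion.
#'
#' @param phase_diff current frame minus reference phase (rad).
#' @param stable_mask logical matrix of pixels unaffected by heating
#'   (non-empty).
#' @return Scalar drift estimate in rad.
#' @export
estimate_drift <- function(phase_diff, stable_mask) {
  stopifnot_same_shape(phase_diff, stable_mask)
  if (!any(stable_mask)) stop("'stable_mask' is empty", call. = FALSE)
  stats::median(phase_diff[stable_mask])
}

#' Initialise the causal temporal low-pass filter
#'
#' Designs a causal Butterworth low-pass (default order 2, cutoff 0.14 Hz)
#' and allocates per-pixel delay registers for streaming direct-form-II
#' transposed updates. The filter has unit DC gain, so steady temperatures
#' pass through unchanged while frame-to-frame noise is attenuated.
#'
#' @param dim image dimensions c(H, W).
#' @param cutoff_hz cutoff frequency in Hz (must be below Nyquist).
#' @param sampling_hz sampling rate in Hz (1 / frame interval).
#' @param order filter order.
#' @return A `filter_state` to be threaded through [lowpass_step()].
#' @export
butter_filter <- function(dim, cutoff_hz = 0.14, sampling_hz = 1,
                          order = 2L) {
  check_positive(cutoff_hz, "cutoff_hz")
  check_positive(sampling_hz, "sampling_hz")
  if (sampling_hz <= 2 * cutoff_hz) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, 2 * cutoff_hz / sampling_hz, type = "low")
  structure(list(
    b = bf$b, a = bf$a,
    z = lapply(seq_len(order), function(i) matrix(0, dim[1], dim[2])),
    dim = dim, cutoff_hz = cutoff_hz, sampling_hz = sampling_hz,
    order = order, primed = FALSE
  ), class = "filter_state")
}

#' One streaming low-pass update
#'
#' Advances the per-pixel IIR filter by one frame. The output at frame t
#' depends only on frames <= t (causal, real-time compatible). On the first
#' frame the registers are primed to the steady state of that frame, so the
#' filter starts from the first observed temperature rather than from zero.
#'
#' @param state a `filter_state` from [butter_filter()].
#' @param x input frame (matrix matching the state dimensions).
#' @return List with the updated `state` and the filtered frame `value`.
#' @export
lowpass_step <- function(state, x) {
  stopifnot(inherits(state, "filter_state"))
  stopifnot_same_shape(x, state$z[[1]])
  b <- state$b; a <- state$a; n <- state$order
  if (!state$primed) {
    # steady-state priming: registers consistent with a constant input x
    for (i in seq_len(n)) {
      state$z[[i]] <- x * sum(b[(i + 1):(n + 1)]) - x * sum(a[(i + 1):(n + 1)])
    }
    state$primed <- TRUE
  }
  y <- b[1] * x + state$z[[1]]
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      state$z[[i]] <- b[i + 1] * x - a[i + 1] * y + state$z[[i + 1]]
    }
  }
  state$z[[n]] <- b[n + 1] * x - a[n + 1] * y
  list(state = state, value = y)
}

#' One temporal phase-unwrapping update
#'
#' Streaming per-pixel unwrapping of a phase series: the change between
#' consecutive raw (wrapped) frames is wrapped into (-pi, pi] and accumulated,
#' which is valid while the true inter-frame phase change stays below pi in
#' magnitude (heating of a few degC per frame is well inside this bound).
#' Spatial unwrapping is not attempted.
#'
#' @param prev_raw,prev_unwrapped previous wrapped and unwrapped frames, or
#'   `NULL` on the first frame.
#' @param cur_raw current wrapped frame (rad).
#' @return The current unwrapped frame.
#' @export
unwrap_step <- function(prev_raw, prev_unwrapped, cur_raw) {
  if (is.null(prev_raw)) return(cur_raw)
  prev_unwrapped + wrap_pi(cur_raw - prev_raw)
}
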