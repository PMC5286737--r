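#' PRFS acquisition parameters
#'
#' Bundles the constants of proton resonance frequency shift thermometry.
#' Temperature change is recovered from phase-image differences as
#' \deqn{\Delta T = (\varphi_t - \varphi_{ref}) \cdot k, \qquad
#'   k = \left(2\pi \cdot \tfrac{\gamma}{2\pi} \cdot \alpha \cdot B_0 \cdot
#'   TE\right)^{-1}}
#' where \eqn{\gamma/2\pi} = 42.58 MHz/T is the proton gyromagnetic ratio,
#' \eqn{\alpha} = -0.0094 ppm/degC the PRF temperature coefficient, \eqn{B_0}
#' the field strength and TE the echo time. With these constants k is
#' negative: heating lowers the phase.
#'
#' @param te echo time in s.
#' @param b0 static field strength in T.
#' @param gamma_over_2pi gyromagnetic ratio over 2 pi, in Hz/T.
#' @param alpha_ppm PRF temperature coefficient in ppm/degC (non-zero).
#' @return An object of class `prfs_params`.
#' @examples
#' prfs_constant(prfs_params(te = 0.018)) # about -14.73 degC/rad at 1.5 T
#' @export
prfs_params <- function(te, b0 = 1.5, gamma_over_2pi = 42.58e6,
                        alpha_ppm = -0.0094) {
  check_positive(te, "te")
  check_positive(b0, "b0")
  check_positive(gamma_over_2pi, "gamma_over_2pi")
  if (!is.finite(alpha_ppm) || alpha_ppm == 0) {
    stop("'alpha_ppm' must be finite and non-zero", call. = FALSE)
  }
  structure(list(te = te, b0 = b0, gamma_over_2pi = gamma_over_2pi,
                 alpha_ppm = alpha_ppm), class = "prfs_params")
}

#' PRFS temperature-to-phase constant k (degC/rad)
#'
#' @param params a [prfs_params()].
#' @return Signed scalar k in degC per radian (negative for the standard
#'   negative PRF coefficient).
#' @export
prfs_constant <- function(params) {
  stopifnot(inherits(params, "prfs_params"))
  1 / (2 * pi * params$gamma_over_2pi * params$alpha_ppm * 1e-6 *
         params$b0 * params$te)
}

#' Convert a corrected phase image to a temperature-change map
#'
#' Elementwise \eqn{\Delta T = (\varphi_t - \varphi_{ref}) \cdot k}. Phases
#' must be temporally unwrapped upstream.
#'
#' @param phase corrected phase image (rad).
#' @param ref_phase reference phase image (rad), same shape.
#' @param k PRFS constant in degC/rad (see [prfs_constant()]).
#' @return Temperature change map in degC.
#' @export
temperature_map <- function(phase, ref_phase, k) {
  stopifnot_same_shape(phase, ref_phase)
  if (any(!is.finite(phase)) || any(!is.finite(ref_phase))) {
    stop("phases must be finite", call. = FALSE)
  }
  (phase - ref_phase) * k
}

#' Per-pixel temporal statistics of a temperature series
#'
#' Computes the temporal mean \eqn{\mu_T} and sample standard deviation
#' \eqn{\sigma_T} on each pixel over a window of frames, and flags pixels
#' whose \eqn{\sigma_T} exceeds the stability threshold (default 7 degC) as
#' excluded from statistical analysis.
#'
#' @param dT 3D array (H x W x frames) of temperature changes, >= 2 frames.
#' @param exclusion_threshold degC; pixels with sigma above it are masked.
#' @return List with `mu_map`, `sigma_map` (degC) and logical
#'   `exclusion_mask`.
#' @export
temperature_stats <- function(dT, exclusion_threshold = 7) {
  d <- dim(dT)
  if (is.null(d) || length(d) != 3 || d[3] < 2) {
    stop("'dT' must be an H x W x frames array with >= 2 frames", call. = FALSE)
  }
  n <- d[3]
  m <- matrix(dT, d[1] * d[2], n)
  mu <- rowMeans(m)
  sigma <- sqrt(rowSums((m - mu)^2) / (n - 1))
  list(mu_map = matrix(mu, d[1], d[2]),
       sigma_map = matrix(sigma, d[1], d[2]),
       exclusion_mask = matrix(sigma > exclusion_threshold, d[1], d[2]))
}

#' Summarise thermometry precision over a region of interest
#'
#' Mirrors the volunteer-style stability analysis: mean \eqn{\sigma_T} and
#' mean \eqn{\mu_T} over an ROI, computed after removing pixels flagged by the
#' stability exclusion rule, together with the excluded-pixel fraction.
#'
#' @param stats output of [temperature_stats()].
#' @param roi logical matrix selecting the region of interest (non-empty).
#' @return A one-row tibble: `mean_sigma_c`, `mean_mu_c`, `frac_excluded`,
#'   `n_pixels`, `n_excluded`.
#' @export
roi_summary <- function(stats, roi) {
  if (!any(roi)) stop("'roi' must contain at least one pixel", call. = FALSE)
  stopifnot_same_shape(stats$sigma_map, roi)
  excl <- stats$exclusion_mask & roi
  keep <- roi & !stats$exclusion_mask
  tibble::tibble(
    mean_sigma_c = mean(stats$sigma_map[keep]),
    mean_mu_c = mean(stats$mu_map[keep]),
    frac_excluded = sum(excl) / sum(roi),
    n_pixels = sum(roi),
    n_excluded = sum(excl)
  )
}
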