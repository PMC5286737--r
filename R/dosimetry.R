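#' Create an empty thermal-dose map
#'
#' Thermal dose is accumulated in cumulative equivalent minutes at 43 degC
#' (CEM43). A constant exposure of 240 min at 43 degC is the lethal
#' threshold; normalized dose divides by 240 so that 1 marks lethality.
#'
#' @param dim image dimensions c(H, W).
#' @param lethal_minutes equivalent minutes at 43 degC taken as lethal
#'   (default 240).
#' @return A `thermal_dose_map` with fields `cem43` (matrix, eq. minutes),
#'   `lethal_minutes`, `sigma_baseline` (degC map or `NULL`), `corrected`
#'   (matrix or `NULL` until [correct_dose()] is applied).
#' @export
dose_map <- function(dim, lethal_minutes = 240) {
  structure(list(
    cem43 = matrix(0, dim[1], dim[2]),
    lethal_minutes = lethal_minutes,
    sigma_baseline = NULL,
    corrected = NULL
  ), class = "thermal_dose_map")
}

#' Normalized thermal dose (1 = lethal threshold)
#' @param dose a `thermal_dose_map`.
#' @param corrected use the uncertainty-corrected dose when available.
#' @return Matrix of dose in lethal-threshold units.
#' @export
dose_normalized <- function(dose, corrected = TRUE) {
  m <- if (corrected && !is.null(dose$corrected)) dose$corrected else dose$cem43
  m / dose$lethal_minutes
}

#' Accumulate one frame of CEM43 thermal dose
#'
#' Streaming (causal) rectangle-rule update of the Sapareto-Dewey cumulative
#' equivalent minutes: each pixel gains `R(T) * dt / 60` equivalent minutes,
#' with `R(T) = 2^(T - 43)` for T >= 43 degC and `4^(T - 43)` below. The
#' update depends only on the current state and frame, so dose over a series
#' is additive over any split of the frames, and is non-decreasing because
#' the integrand is strictly positive.
#'
#' @param dose a `thermal_dose_map`.
#' @param T_abs absolute temperature map in degC (reference body temperature
#'   plus measured temperature change), finite.
#' @param dt frame duration in s (> 0).
#' @return The updated `thermal_dose_map`.
#' @export
dose_step <- function(dose, T_abs, dt) {
  stopifnot(inherits(dose, "thermal_dose_map"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("'dt' must be a positive duration in seconds", call. = FALSE)
  }
  if (any(!is.finite(T_abs))) stop("'T_abs' must be finite", call. = FALSE)
  stopifnot_same_shape(dose$cem43, as.matrix(T_abs))
  r <- ifelse(T_abs >= 43, 2^(T_abs - 43), 4^(T_abs - 43))
  dose$cem43 <- dose$cem43 + r * dt / 60
  dose$corrected <- NULL # stale after new accumulation
  dose
}

#' Apply the temperature-uncertainty correction to a dose map
#'
#' Thermometry noise propagates exponentially into thermal dose, so the dose
#' is attenuated by the per-pixel measurement uncertainty:
#' \deqn{TD_{corrected}(x, y) = TD(x, y) \cdot
#'   e^{-0.5\,(\ln(2)\,\sigma_T(x, y))^2}}
#' with \eqn{\sigma_T} the temperature standard deviation computed before RF
#' delivery (over 20 repetitions in the default pipeline). The factor lies in
#' (0, 1], so the corrected dose never exceeds the raw dose; pixels with
#' unstable thermometry (large \eqn{\sigma_T}) have their dose suppressed.
#'
#' @param dose a `thermal_dose_map`.
#' @param sigma_baseline per-pixel temperature standard deviation map (degC,
#'   non-negative); defaults to `dose$sigma_baseline`.
#' @return The `thermal_dose_map` with `corrected` (and `sigma_baseline`)
#'   filled in.
#' @export
correct_dose <- function(dose, sigma_baseline = dose$sigma_baseline) {
  stopifnot(inherits(dose, "thermal_dose_map"))
  if (is.null(sigma_baseline)) {
    stop("'sigma_baseline' is required (compute it over the pre-RF frames)",
         call. = FALSE)
  }
  if (any(sigma_baseline < 0)) {
    stop("'sigma_baseline' must be non-negative", call. = FALSE)
  }
  stopifnot_same_shape(dose$cem43, as.matrix(sigma_baseline))
  dose$sigma_baseline <- sigma_baseline
  dose$corrected <- dose$cem43 * exp(-0.5 * (log(2) * sigma_baseline)^2)
  dose
}

#' Extract the lethal lesion mask from a dose map
#'
#' Thresholds the (corrected, when available) normalized dose at the lethal
#' level and keeps the 8-connected component containing the seed point — or,
#' when the seed is not supra-threshold, the component nearest to it. Other
#' supra-threshold components (e.g. noise speckle far from the catheter) are
#' discarded and counted in the `"n_discarded"` attribute. An empty mask is a
#' valid outcome: the ablation did not produce a lesion.
#'
#' @param dose a `thermal_dose_map` (or a plain matrix of normalized dose).
#' @param threshold lethal threshold in normalized units (default 1.0).
#' @param seed_point optional (row, col) of the expected hotspot (catheter
#'   tip); defaults to the largest component.
#' @return Logical lesion mask with attribute `"n_discarded"`.
#' @export
lethal_mask <- function(dose, threshold = 1.0, seed_point = NULL) {
  check_positive(threshold, "threshold")
  norm <- if (inherits(dose, "thermal_dose_map")) dose_normalized(dose)
    else dose
  supra <- norm >= threshold
  if (!any(supra)) {
    out <- supra
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  lab <- EBImage::bwlabel(supra * 1)
  labs <- sort(unique(lab[lab > 0]))
  pick <- if (!is.null(seed_point)) {
    seed_lab <- lab[seed_point[1], seed_point[2]]
    if (seed_lab > 0) seed_lab else {
      # nearest component to the seed, by minimum pixel distance
      dists <- vapply(labs, function(l) {
        idx <- which(lab == l, arr.ind = TRUE)
        min(sqrt((idx[, 1] - seed_point[1])^2 + (idx[, 2] - seed_point[2])^2))
      }, numeric(1))
      labs[which.min(dists)]
    }
  } else {
    sizes <- vapply(labs, function(l) sum(lab == l), numeric(1))
    labs[which.max(sizes)]
  }
  out <- lab == pick
  attr(out, "n_discarded") <- length(labs) - 1L
  out
}

#' Principal-axis dimensions of a lesion mask
#'
#' The lesion's largest and smallest dimensions are measured along the
#' principal axes of its pixel-center coordinates: full extents
#' (max - min projection plus one pixel spacing, so a single pixel measures
#' one pixel across), in mm. For compact, ruler-measurable blobs these
#' coincide closely with caliper measurements.
#'
#' @param mask logical lesion mask.
#' @param pixel_spacing pixel size in mm.
#' @return A one-row tibble (`lesion_measure`): `largest_mm`, `smallest_mm`,
#'   `area_mm2`, `centroid_row`, `centroid_col`, `n_pixels`. An empty mask
#'   yields `n_pixels = 0` and `NA` dimensions — a distinguished "no lesion"
#'   result, not an error.
#' @export
lesion_dimensions <- function(mask, pixel_spacing) {
  check_positive(pixel_spacing, "pixel_spacing")
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) {
    return(tibble::tibble(largest_mm = NA_real_, smallest_mm = NA_real_,
                          area_mm2 = 0, centroid_row = NA_real_,
                          centroid_col = NA_real_, n_pixels = 0L))
  }
  xy <- cbind(idx[, 2], idx[, 1]) * pixel_spacing # (x, y) in mm
  ctr <- colMeans(xy)
  if (n == 1) {
    ext <- c(pixel_spacing, pixel_spacing)
  } else {
    cen <- sweep(xy, 2, ctr)
    ev <- eigen(crossprod(cen) / n, symmetric = TRUE)$vectors
    proj <- cen %*% ev
    ext <- sort(apply(proj, 2, function(p) diff(range(p))) + pixel_spacing,
                decreasing = TRUE)
  }
  tibble::tibble(
    largest_mm = ext[1], smallest_mm = ext[2],
    area_mm2 = n * pixel_spacing^2,
    centroid_row = ctr[2] / pixel_spacing,
    centroid_col = ctr[1] / pixel_spacing,
    n_pixels = n
  )
}
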