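#' Construct a frame series from magnitude and phase arrays
#'
#' @param magnitude,phase H x W x frames arrays (phase in radians).
#' @param times frame timestamps in s (default: 1 s spacing from 0).
#' @param pixel_spacing in-plane pixel size in mm.
#' @return A `frame_series`.
#' @export
frame_series <- function(magnitude, phase,
                         times = (seq_len(dim(magnitude)[3]) - 1),
                         pixel_spacing = 0.8) {
  if (!identical(dim(magnitude), dim(phase)) || length(dim(magnitude)) != 3) {
    stop("magnitude and phase must be H x W x frames arrays of equal size",
         call. = FALSE)
  }
  if (length(times) != dim(magnitude)[3]) {
    stop("one timestamp per frame required", call. = FALSE)
  }
  structure(list(magnitude = magnitude, phase = phase, times = times,
                 pixel_spacing = pixel_spacing), class = "frame_series")
}

write_map_nifti <- function(map, path, pixel_spacing) {
  img <- RNifti::asNifti(map)
  nd <- length(dim(map))
  RNifti::pixdim(img) <- c(rep(pixel_spacing, 2), rep(1, nd - 2))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a dynamic series as magnitude and phase NIfTI volumes
#'
#' The 2D+t stacks are stored as 3D NIfTI-1 files (phase in radians, floating
#' point) with the pixel spacing in the header and the frame times in a JSON
#' sidecar.
#'
#' @param series a `frame_series`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_series_nifti <- function(series, dir, prefix = "series") {
  stopifnot(inherits(series, "frame_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_mag <- file.path(dir, paste0(prefix, "_magnitude.nii.gz"))
  p_phs <- file.path(dir, paste0(prefix, "_phase.nii.gz"))
  p_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  write_map_nifti(series$magnitude, p_mag, series$pixel_spacing)
  write_map_nifti(series$phase, p_phs, series$pixel_spacing)
  jsonlite::write_json(list(times = series$times,
                            pixel_spacing = series$pixel_spacing),
                       p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(magnitude = p_mag, phase = p_phs, meta = p_meta))
}

#' Read a dynamic series written by [write_series_nifti()]
#'
#' @param dir directory holding the magnitude/phase NIfTI pair.
#' @param prefix file-name prefix used at write time.
#' @return A `frame_series`.
#' @export
read_series_nifti <- function(dir, prefix = "series") {
  mag <- RNifti::readNifti(file.path(dir, paste0(prefix, "_magnitude.nii.gz")))
  phs <- RNifti::readNifti(file.path(dir, paste0(prefix, "_phase.nii.gz")))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  sp <- RNifti::pixdim(mag)[1]
  times <- (seq_len(dim(mag)[3]) - 1)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    sp <- meta$pixel_spacing
    times <- meta$times
  }
  frame_series(unclass(mag)[, , , drop = FALSE],
               unclass(phs)[, , , drop = FALSE],
               times = times, pixel_spacing = sp)
}

#' Write a pipeline report to disk
#'
#' Writes the lesion measures as CSV, a JSON summary (peak temperature, dose
#' statistics, excluded-pixel fraction, lesion dimensions — with an explicit
#' "no lesion" record when nothing reached the lethal threshold), the result
#' maps (final temperature, mu_T, sigma_T, CEM43 and corrected dose) as
#' NIfTI, and optionally a PNG overlay of the lesion on the final
#' temperature map.
#'
#' @param result a `ctm_result` from [run_pipeline()].
#' @param dir output directory.
#' @param png also render a quick-look PNG overlay.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir, png = FALSE) {
  stopifnot(inherits(result, "ctm_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- result$config$pixel_spacing
  paths <- c(lesion = file.path(dir, "lesion.csv"),
             summary = file.path(dir, "summary.json"))
  utils::write.csv(result$lesion, paths[["lesion"]], row.names = FALSE)
  nT <- dim(result$temperature$dT)[3]
  summary <- list(
    n_frames_emitted = nT,
    max_dT_c = max(result$temperature$dT),
    mean_sigma_c = mean(result$temperature$sigma_map),
    frac_excluded = mean(result$temperature$exclusion_mask),
    peak_dose_normalized = max(dose_normalized(result$dose)),
    lesion = if (result$lesion$n_pixels > 0) as.list(result$lesion)
      else list(status = "no lesion", n_pixels = 0)
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  maps <- list(dT_final = result$temperature$dT[, , nT],
               mu_T = result$temperature$mu_map,
               sigma_T = result$temperature$sigma_map,
               cem43 = result$dose$cem43,
               dose_corrected = result$dose$corrected)
  for (nm in names(maps)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_map_nifti(maps[[nm]], p, sp)
    paths[nm] <- p
  }
  if (png) {
    p <- file.path(dir, "overlay.png")
    grDevices::png(p, width = 640, height = 640)
    plot_map(result$temperature$dT[, , nT], main = "Final dT (degC)")
    if (result$lesion$n_pixels > 0) {
      contour(seq_len(nrow(result$lesion_mask)),
              seq_len(ncol(result$lesion_mask)),
              result$lesion_mask * 1, levels = 0.5, add = TRUE,
              drawlabels = FALSE, col = "red", lwd = 2)
    }
    grDevices::dev.off()
    paths["overlay"] <- p
  }
  invisible(paths)
}

#' Write a concordance report (agreement statistics) as CSV
#'
#' @param stats an `agreement_stats` object.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_concordance_csv <- function(stats, path) {
  utils::write.csv(glance(stats), path, row.names = FALSE)
  invisible(path)
}
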