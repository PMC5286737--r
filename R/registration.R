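#' Estimate dense in-plane motion between two magnitude images
#'
#' Variational optical flow in the Horn-Schunck family: minimises intensity
#' mismatch plus `smoothness` times the squared gradient of the field, solved
#' by Jacobi iterations on a 3-level coarse-to-fine pyramid with Gaussian
#' pre-smoothing. The returned displacement maps reference positions to
#' sampling positions in the moving image, i.e. `warp(moving, field)`
#' resamples the moving image onto the reference anatomy.
#'
#' @param moving,reference magnitude images, same shape, non-negative.
#' @param smoothness regularisation weight (Horn-Schunck alpha^2 uses
#'   `smoothness^2`); larger gives smoother fields.
#' @param n_iter Jacobi iterations per pyramid level.
#' @param levels number of pyramid levels (downsampling by 2 per level).
#' @param pre_sigma Gaussian pre-smoothing (pixels) applied at full resolution.
#' @return A `motion_field`: list with displacement matrices `dx` (columns)
#'   and `dy` (rows) in pixels, plus a `converged` attribute with the final
#'   mean absolute update per level.
#' @export
estimate_flow <- function(moving, reference, smoothness = 0.2,
                          n_iter = 100L, levels = 3L, pre_sigma = 1) {
  stopifnot_same_shape(moving, reference)
  if (any(moving < 0) || any(reference < 0)) {
    stop("magnitude images must be non-negative", call. = FALSE)
  }
  if (all(moving == 0) || all(reference == 0)) {
    warning("all-zero image: no gradient information, returning zero field")
    z <- matrix(0, nrow(moving), ncol(moving))
    return(motion_field(z, z))
  }
  scale <- max(reference, moving)
  mv <- gauss_blur(moving / scale, pre_sigma)
  rf <- gauss_blur(reference / scale, pre_sigma)

  # build pyramid (level 1 = coarsest)
  pyr_m <- list(mv); pyr_r <- list(rf)
  lv <- 1L
  while (lv < levels && min(dim(pyr_m[[1]])) >= 24) {
    pyr_m <- c(list(downsample2(pyr_m[[1]])), pyr_m)
    pyr_r <- c(list(downsample2(pyr_r[[1]])), pyr_r)
    lv <- lv + 1L
  }

  u <- matrix(0, nrow(pyr_m[[1]]), ncol(pyr_m[[1]]))
  v <- u
  conv <- numeric(length(pyr_m))
  for (l in seq_along(pyr_m)) {
    if (l > 1) {
      u <- 2 * resize_bilinear(u, dim(pyr_m[[l]]))
      v <- 2 * resize_bilinear(v, dim(pyr_m[[l]]))
    }
    res <- hs_refine(pyr_m[[l]], pyr_r[[l]], u, v, smoothness, n_iter)
    u <- res$u; v <- res$v; conv[l] <- res$delta
  }
  fld <- motion_field(dx = u, dy = v)
  attr(fld, "converged") <- conv
  fld
}

motion_field <- function(dx, dy, frame_index = NA_integer_) {
  stopifnot_same_shape(dx, dy)
  structure(list(dx = dx, dy = dy, frame_index = frame_index),
            class = "motion_field")
}

downsample2 <- function(m) {
  s <- gauss_blur(m, 1)
  s[seq(1, nrow(s), by = 2), seq(1, ncol(s), by = 2), drop = FALSE]
}

resize_bilinear <- function(m, new_dim) {
  nr <- new_dim[1]; nc <- new_dim[2]
  rr <- matrix(seq(1, nrow(m), length.out = nr), nr, nc)
  cc <- matrix(seq(1, ncol(m), length.out = nc), nr, nc, byrow = TRUE)
  out <- bilinear_sample(m, rr, cc)
  attr(out, "valid") <- NULL
  out
}

# One incremental Horn-Schunck solve: warp moving by the current field, then
# Jacobi-iterate the optical-flow normal equations for the residual flow.
hs_refine <- function(moving, reference, u, v, smoothness, n_iter) {
  warped <- bilinear_sample(moving,
                            row(moving) + v, col(moving) + u)
  attr(warped, "valid") <- NULL
  avg <- (warped + reference) / 2
  Ix <- (shift_mat(avg, 0, 1) - shift_mat(avg, 0, -1)) / 2
  Iy <- (shift_mat(avg, 1, 0) - shift_mat(avg, -1, 0)) / 2
  It <- warped - reference
  denom <- smoothness^2 + Ix^2 + Iy^2
  du <- matrix(0, nrow(moving), ncol(moving))
  dv <- du
  delta <- Inf
  for (it in seq_len(n_iter)) {
    dub <- hs_avg(du); dvb <- hs_avg(dv)
    tt <- (Ix * dub + Iy * dvb + It) / denom
    du_new <- dub - Ix * tt
    dv_new <- dvb - Iy * tt
    delta <- mean(abs(du_new - du)) + mean(abs(dv_new - dv))
    du <- du_new; dv <- dv_new
    if (delta < 1e-5) break
  }
  list(u = u + du, v = v + dv, delta = delta)
}

# Horn-Schunck neighbourhood average (weights 1/6 edge, 1/12 diagonal).
hs_avg <- function(m) {
  (shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
     shift_mat(m, 0, 1) + shift_mat(m, 0, -1)) / 6 +
    (shift_mat(m, 1, 1) + shift_mat(m, 1, -1) +
       shift_mat(m, -1, 1) + shift_mat(m, -1, -1)) / 12
}

#' Warp an image with a motion field
#'
#' Bilinear resampling at the displaced coordinates: `out[r, c] =
#' image[r + dy, c + dx]`. Out-of-bounds samples take nearest-edge values and
#' are flagged in the `"valid"` attribute. Phase images are warped through
#' their complex representation (cos, sin) so that wrap discontinuities do not
#' bleed through the interpolation, then re-extracted with `atan2`.
#'
#' @param image matrix to resample.
#' @param field a `motion_field` with the same shape.
#' @param phase logical; set `TRUE` when `image` is a wrapped phase map (rad).
#' @return Resampled matrix with a logical `"valid"` attribute.
#' @export
warp <- function(image, field, phase = FALSE) {
  stopifnot(inherits(field, "motion_field"))
  stopifnot_same_shape(image, field$dx)
  if (any(!is.finite(field$dx)) || any(!is.finite(field$dy))) {
    stop("motion field must be finite", call. = FALSE)
  }
  rr <- row(image) + field$dy
  cc <- col(image) + field$dx
  if (phase) {
    re <- bilinear_sample(cos(image), rr, cc)
    im <- bilinear_sample(sin(image), rr, cc)
    out <- atan2(im, re)
    attr(out, "valid") <- attr(re, "valid")
    out
  } else {
    bilinear_sample(image, rr, cc)
  }
}

#' Principal-component basis of a set of motion fields
#'
#' Vectorises each field (dx then dy), removes the mean field, and extracts
#' the leading principal components by singular value decomposition. The
#' components are orthonormal under the per-pixel inner product and ordered
#' by decreasing explained variance.
#'
#' @param fields list of `motion_field`s (at least `n_components + 1`).
#' @param n_components number of modes to keep.
#' @return A `motion_basis`: `mean_field`, `components` (list of
#'   `motion_field`s), `explained_variance` (fractions of total variance).
#' @export
build_motion_basis <- function(fields, n_components = 2L) {
  n <- length(fields)
  if (n < n_components + 1) {
    stop("need at least n_components + 1 fields", call. = FALSE)
  }
  d <- dim(fields[[1]]$dx)
  X <- t(vapply(fields, function(f) c(f$dx, f$dy), numeric(2 * prod(d))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (n_components > min(dim(Xc))) {
    stop("n_components exceeds the available rank", call. = FALSE)
  }
  sv <- svd(Xc, nu = 0, nv = n_components)
  total <- sum(Xc^2)
  ev <- if (total > 0) (sv$d[seq_len(n_components)]^2) / total else
    rep(0, n_components)
  comps <- lapply(seq_len(n_components), function(j) {
    vec <- sv$v[, j]
    motion_field(dx = matrix(vec[seq_len(prod(d))], d[1], d[2]),
                 dy = matrix(vec[prod(d) + seq_len(prod(d))], d[1], d[2]))
  })
  structure(list(
    mean_field = motion_field(dx = matrix(mu[seq_len(prod(d))], d[1], d[2]),
                              dy = matrix(mu[prod(d) + seq_len(prod(d))],
                                          d[1], d[2])),
    components = comps,
    explained_variance = ev
  ), class = "motion_basis")
}

#' Project a motion field onto a learned basis
#'
#' Inner products of the mean-removed field with each basis component. The
#' coefficients parameterise the motion state of a frame and drive the
#' susceptibility phase model.
#'
#' @param field a `motion_field`.
#' @param basis a `motion_basis` from [build_motion_basis()].
#' @return Numeric coefficient vector, one per component.
#' @export
project_motion <- function(field, basis) {
  stopifnot(inherits(basis, "motion_basis"))
  if (length(basis$components) == 0) stop("empty basis", call. = FALSE)
  stopifnot_same_shape(field$dx, basis$mean_field$dx)
  vec <- c(field$dx - basis$mean_field$dx, field$dy - basis$mean_field$dy)
  vapply(basis$components, function(cp) sum(vec * c(cp$dx, cp$dy)), numeric(1))
}

#' Reconstruct a motion field from basis coefficients
#'
#' Rank-limited reconstruction `mean_field + sum(coeff[j] * component[j])`,
#' used to denoise per-frame flow estimates during the intervention.
#'
#' @param coeffs coefficient vector (one per basis component).
#' @param basis a `motion_basis`.
#' @return A `motion_field`.
#' @export
reconstruct_motion <- function(coeffs, basis) {
  stopifnot(length(coeffs) == length(basis$components))
  dx <- basis$mean_field$dx
  dy <- basis$mean_field$dy
  for (j in seq_along(coeffs)) {
    dx <- dx + coeffs[j] * basis$components[[j]]$dx
    dy <- dy + coeffs[j] * basis$components[[j]]$dy
  }
  motion_field(dx, dy)
}
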