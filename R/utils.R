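# Internal array helpers shared across the pipeline.

# Wrap angles into (-pi, pi].
wrap_pi <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Shift a matrix by (dr, dc) integer pixels with replicate (nearest-edge) padding.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur via banded smoothing matrices (replicate edges are
# approximated by renormalising truncated kernels, which keeps DC gain 1).
smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-hw:hw), 1L), n)
    for (t in seq_along(j)) S[i, j[t]] <- S[i, j[t]] + k[t]
  }
  S / rowSums(S)
}

gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Sr <- smoothing_matrix(nrow(m), sigma)
  Sc <- smoothing_matrix(ncol(m), sigma)
  Sr %*% m %*% t(Sc)
}

# Bilinear sampling of `img` at (row, col) coordinates given as matrices the
# same shape as the output. Out-of-bounds coordinates are clamped to the edge;
# the attached "valid" attribute marks in-bounds samples.
bilinear_sample <- function(img, rr, cc) {
  nr <- nrow(img); nc <- ncol(img)
  out_dim <- dim(rr)
  valid <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  rr <- pmin(pmax(rr, 1), nr)
  cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rr), nr - 1L); r1 <- r0 + 1
  c0 <- pmin(floor(cc), nc - 1L); c1 <- c0 + 1
  fr <- rr - r0; fc <- cc - c0
  v00 <- img[cbind(as.vector(r0), as.vector(c0))]
  v10 <- img[cbind(as.vector(r1), as.vector(c0))]
  v01 <- img[cbind(as.vector(r0), as.vector(c1))]
  v11 <- img[cbind(as.vector(r1), as.vector(c1))]
  out <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  out <- matrix(out, out_dim[1], out_dim[2])
  attr(out, "valid") <- valid
  out
}

check_positive <- function(x, name, strict = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) < 1 || anyNA(x)) {
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  }
  if (finite && any(!is.finite(x)) && !identical(x, Inf)) {
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  }
  if (strict && any(x <= 0)) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (!strict && any(x < 0)) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  invisible(TRUE)
}
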