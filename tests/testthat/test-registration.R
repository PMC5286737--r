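template_64 <- function(shift_mm = c(0, 0)) {
  phantom_template(quiet_config(grid_size = c(64L, 64L)), shift_mm)
}

test_that("flow on identical images is zero and shapes are validated", {
  A <- template_64()
  f <- estimate_flow(A, A)
  expect_lt(max(abs(f$dx)), 0.05)
  expect_lt(max(abs(f$dy)), 0.05)
  expect_error(estimate_flow(A, A[1:32, ]), "dimensions")
  expect_warning(estimate_flow(matrix(0, 16, 16), matrix(0, 16, 16)),
                 "zero")
})

test_that("flow recovers a known integer shift within half a pixel", {
  A <- template_64()
  # content moved +3 px along x: with the sampling convention
  # moving(x + d) = reference(x), the recovered dx is -3
  ref <- template_64(shift_mm = c(0, 3 * 0.8))
  f <- estimate_flow(A, ref)
  interior <- interior_mask(c(64, 64), 16)
  expect_equal(mean(f$dx[interior]), -3, tolerance = 0.5 / 3)
  expect_lt(abs(mean(f$dy[interior])), 0.2)
})

test_that("flow is approximately shift-equivariant on translated images", {
  A <- template_64()
  interior <- interior_mask(c(64, 64), 16)
  for (s_px in c(1, 2)) {
    ref <- template_64(shift_mm = c(s_px * 0.8, 0))
    f <- estimate_flow(A, ref)
    expect_equal(mean(f$dy[interior]), -s_px, tolerance = 0.25)
  }
})

test_that("registration halves the intensity mismatch on a breathing phantom", {
  # Monte-Carlo over seeds at the design respiratory amplitude
  interior <- interior_mask(c(48, 48), 10)
  for (seed in 1:10) {
    cfg <- phantom_config(grid_size = c(48, 48), n_frames = 8,
                          resp_amplitude = 5, snr = 60, drift_rate = 0,
                          heat_peak = 0, heat_onset_frame = 4,
                          heat_duration_frames = 1, seed = seed)
    g <- generate_series(cfg)
    mov <- g$series$magnitude[, , 4] # near peak displacement
    ref <- g$series$magnitude[, , 1]
    w <- warp(mov, estimate_flow(mov, ref))
    mse0 <- mean((mov - ref)[interior]^2)
    mse1 <- mean((w - ref)[interior]^2)
    expect_lt(mse1, 0.5 * mse0)
  }
})

test_that("warping preserves constants, identities and total intensity", {
  A <- template_64()
  zero <- motion_field(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_equal(warp(A, zero), A, ignore_attr = TRUE)

  cphase <- matrix(0.7, 64, 64)
  fld <- motion_field(matrix(1.3, 64, 64), matrix(-0.6, 64, 64))
  expect_equal(warp(cphase, fld, phase = TRUE), matrix(0.7, 64, 64),
               ignore_attr = TRUE, tolerance = 1e-12)

  # total intensity away from the edges conserved within interpolation blur
  w <- warp(A, fld)
  interior <- interior_mask(c(64, 64), 6)
  expect_equal(sum(w[interior]), sum(A[interior]), tolerance = 0.02)
})

test_that("warp round-trips through the inverse field on a smooth image", {
  A <- template_64()
  fld <- motion_field(matrix(2.1, 64, 64), matrix(-1.4, 64, 64))
  inv <- motion_field(-fld$dx, -fld$dy)
  back <- warp(warp(A, fld), inv)
  interior <- interior_mask(c(64, 64), 6)
  rmse <- sqrt(mean((back - A)[interior]^2)) / sqrt(mean(A[interior]^2))
  expect_lt(rmse, 0.02)
})

test_that("phase warping does not smear wrap discontinuities", {
  wrap_to_pi_test <- function(x) x - 2 * pi * round(x / (2 * pi))
  # a wrapped phase ramp: direct bilinear interpolation across a wrap would
  # average +pi with -pi; complex warping shifts the ramp cleanly
  ramp <- matrix(seq(-pi, pi, length.out = 64), 64, 64, byrow = TRUE)
  wrapped <- atan2(sin(3 * ramp), cos(3 * ramp))
  fld <- motion_field(matrix(0.5, 64, 64), matrix(0, 64, 64))
  w <- warp(wrapped, fld, phase = TRUE)
  step <- diff(ramp[1, 1:2])
  expected <- atan2(sin(3 * (ramp + 0.5 * step)), cos(3 * (ramp + 0.5 * step)))
  err <- abs(wrap_to_pi_test(w[10, 5:60] - expected[10, 5:60]))
  expect_lt(max(err), 0.05)
})

test_that("motion basis handles degenerate and rank-1 field sets", {
  d <- c(16, 16)
  common <- motion_field(matrix(1.5, d[1], d[2]), matrix(-0.5, d[1], d[2]))
  basis0 <- build_motion_basis(rep(list(common), 5), 2)
  expect_equal(basis0$explained_variance, c(0, 0))
  expect_equal(basis0$mean_field$dx, common$dx)

  # rank-1: fields = c_t * B
  B <- motion_field(matrix(rnorm(256), 16), matrix(rnorm(256), 16))
  cs <- c(-2, -1, 0.5, 1, 3)
  fields <- lapply(cs, function(ct) motion_field(ct * B$dx, ct * B$dy))
  basis1 <- build_motion_basis(fields, 2)
  expect_gt(basis1$explained_variance[1], 0.999)
  # component proportional to B (up to sign)
  v <- c(basis1$components[[1]]$dx, basis1$components[[1]]$dy)
  b <- c(B$dx, B$dy)
  expect_gt(abs(sum(v * b)) / sqrt(sum(b^2)), 0.999)

  expect_error(build_motion_basis(fields, 5), "rank|fields")
})

test_that("components are orthonormal and projection round-trips", {
  set.seed(42)
  fields <- lapply(1:12, function(i) {
    motion_field(matrix(rnorm(64), 8), matrix(rnorm(64), 8))
  })
  basis <- build_motion_basis(fields, 3)
  for (a in 1:3) for (b in 1:3) {
    ip <- sum(c(basis$components[[a]]$dx, basis$components[[a]]$dy) *
                c(basis$components[[b]]$dx, basis$components[[b]]$dy))
    expect_equal(ip, as.numeric(a == b), tolerance = 1e-10)
  }

  expect_equal(project_motion(basis$mean_field, basis), rep(0, 3),
               tolerance = 1e-10)
  f2 <- reconstruct_motion(c(2, 0, 0), basis)
  expect_equal(project_motion(f2, basis), c(2, 0, 0), tolerance = 1e-10)

  # rank-limited reconstruction reproduces the projected part exactly
  f <- fields[[1]]
  cf <- project_motion(f, basis)
  rec <- reconstruct_motion(cf, basis)
  expect_equal(project_motion(rec, basis), cf, tolerance = 1e-10)
})

test_that("sinusoidal phantom motion concentrates in one principal mode", {
  for (seed in 1:5) {
    cfg <- phantom_config(grid_size = c(32, 32), n_frames = 20,
                          resp_amplitude = 4, snr = 80, drift_rate = 0,
                          heat_peak = 0, heat_onset_frame = 10,
                          heat_duration_frames = 1, seed = seed)
    g <- generate_series(cfg)
    ref <- g$series$magnitude[, , 1]
    fields <- lapply(1:20, function(i) {
      estimate_flow(g$series$magnitude[, , i], ref)
    })
    basis <- build_motion_basis(fields, 2)
    expect_gt(basis$explained_variance[1], 0.95)
  }
})
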