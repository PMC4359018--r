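test_that("larmor scale converts ppm offsets to Hz at the proton ratio", {
  expect_equal(larmor_scale(7), 42.577 * 7)
  # a 0.01 ppm offset at 7 T is approximately a 3 Hz shift
  expect_equal(larmor_scale(7) * 0.01, 2.98039, tolerance = 1e-6)
  expect_equal(round(larmor_scale(7) * 0.01), 3)
  expect_error(larmor_scale(0), "positive")
  expect_error(larmor_scale(-1), "positive")
})

test_that("isotropic dipole kernel takes its characteristic values", {
  g <- grid_spec(c(16, 16, 16), 1, 1)
  ctx <- field_context(B0_direction = c(0, 0, 1))
  D <- iso_kernel(g, ctx, padded = FALSE)
  # k parallel to B0 -> -2/3; k perpendicular -> 1/3; k = 0 -> 0
  expect_equal(D[1, 1, 2], -2 / 3)
  expect_equal(D[2, 1, 1], 1 / 3)
  expect_equal(D[1, 2, 1], 1 / 3)
  expect_equal(D[1, 1, 1], 0)
  # magic angle: (k.h)^2/|k|^2 = 1/3
  h <- c(sqrt(2 / 3), 0, sqrt(1 / 3))
  Dm <- iso_kernel(g, field_context(B0_direction = h), padded = FALSE)
  expect_equal(Dm[1, 1, 2], 1 / 3 - 1 / 3, tolerance = 1e-12)
})

test_that("sphere field matches the Lorentz identity and the external dipole", {
  g <- grid_spec(c(48, 48, 48), 1, 2)
  sph <- sphere_mask_at(g, 9)
  ctx <- field_context()
  chi0 <- 0.1
  f <- simulate_iso_field(scalar_volume(chi0 * sph, g, "ppm"), ctx)
  # internal mean shift vanishes for a sphere
  expect_lt(abs(mean(f$values[sph])), 0.01 * chi0 * ctx$larmor)
  # external field matches the analytic point dipole beyond 2 radii
  co <- qsmsim:::.centered_coords(g)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  ext <- r >= 18 & r <= 20
  fd <- chi0 * ctx$larmor * sum(sph) / (4 * pi) * (3 * (co$z / r)^2 - 1) / r^3
  expect_lt(relative_rms(f$values[ext], fd[ext]), 0.05)
  # zero susceptibility gives a zero field
  f0 <- simulate_iso_field(scalar_volume(array(0, dim = g$shape), g, "ppm"), ctx)
  expect_equal(max(abs(f0$values)), 0)
})

test_that("axis-periodic cylinder follows (3cos^2-1)/6 across angles", {
  g <- grid_spec(c(48, 48, 16), 1, c(2, 2, 1))
  co <- qsmsim:::.centered_coords(g)
  cyl <- (co$x^2 + co$y^2) <= 36
  core <- (co$x^2 + co$y^2) <= 9
  chi0 <- 0.1
  vol <- scalar_volume(chi0 * cyl, g, "ppm")
  for (th in c(0, 30, 54.7356103, 90)) {
    ctx <- field_context(B0_direction = polar_axis(th))
    f <- simulate_iso_field(vol, ctx)
    pred <- chi0 * ctx$larmor * (3 * cos(th * pi / 180)^2 - 1) / 6
    tol <- if (abs(pred) < 1e-6) 0.005 else 0.02
    expect_lt(abs(mean(f$values[core]) - pred), tol * chi0 * ctx$larmor)
  }
})

test_that("forward models are linear and respect the trace decomposition", {
  sh <- c(20, 20, 20)
  g <- grid_spec(sh, 1, 2)
  ctx <- field_context(B0_direction = c(0.2, -0.3, 1))
  set.seed(11)
  c1 <- array(rnorm(prod(sh), sd = 0.05), dim = sh)
  c2 <- array(rnorm(prod(sh), sd = 0.05), dim = sh)
  f1 <- simulate_iso_field(scalar_volume(c1, g, "ppm"), ctx)$values
  f2 <- simulate_iso_field(scalar_volume(c2, g, "ppm"), ctx)$values
  f12 <- simulate_iso_field(scalar_volume(2 * c1 - 3 * c2, g, "ppm"), ctx)$values
  expect_lt(relative_rms(f12, 2 * f1 - 3 * f2), 1e-9)

  # tensor_forward of traceless part + iso field of trace/3 = full forward
  comps <- lapply(1:6, function(i) array(rnorm(prod(sh), sd = 0.02), dim = sh))
  X <- symmetric_tensor_volume(comps[[1]], comps[[2]], comps[[3]],
                               comps[[4]], comps[[5]], comps[[6]], g)
  tr3 <- (comps[[1]] + comps[[2]] + comps[[3]]) / 3
  X0 <- symmetric_tensor_volume(comps[[1]] - tr3, comps[[2]] - tr3,
                                comps[[3]] - tr3, comps[[4]], comps[[5]],
                                comps[[6]], g)
  f_full <- tensor_forward(X, ctx)$values
  f_split <- tensor_forward(X0, ctx)$values +
    simulate_iso_field(scalar_volume(tr3, g, "ppm"), ctx)$values
  expect_lt(relative_rms(f_split, f_full), 1e-9)

  # isotropic tensor reduces exactly to the scalar model
  Xi <- cylsym_tensor(c1, 0, c(0, 0, 1), g)
  expect_lt(max(abs(tensor_forward(Xi, ctx)$values - f1)), 1e-10)
})

test_that("cylindrically symmetric kernel agrees with the tensor model", {
  sh <- c(32, 32, 32)
  g <- grid_spec(sh, 1, 2)
  ctx <- field_context(B0_direction = c(0.1, 0.2, 0.97))
  set.seed(7)
  chiA <- array(rnorm(prod(sh), sd = 0.02) * (runif(prod(sh)) > 0.5), dim = sh)
  ax <- c(1, 2, 2) / 3
  f_cyl <- cylsym_aniso_field(scalar_volume(chiA, g, "ppm"), ax, ctx)$values
  f_ten <- tensor_forward(cylsym_tensor(0, chiA, ax, g), ctx)$values
  expect_lt(relative_rms(f_cyl, f_ten), 1e-10)
  # zero anisotropy gives a zero field
  fz <- cylsym_aniso_field(scalar_volume(array(0, dim = sh), g, "ppm"),
                           c(0, 0, 1), ctx)
  expect_equal(max(abs(fz$values)), 0)
  expect_error(cylsym_aniso_field(scalar_volume(chiA, g, "ppm"),
                                  c(1, 1, 1), ctx), "unit")
})

test_that("uniform zero-trace tensor sphere has no internal mean shift", {
  g <- grid_spec(c(40, 40, 40), 1, 2)
  sph <- sphere_mask_at(g, 8)
  ctx <- field_context()
  f <- cylsym_aniso_field(scalar_volume(0.1 * sph, g, "ppm"),
                          polar_axis(35, 20), ctx)
  expect_lt(abs(mean(f$values[sph])), 0.01 * 0.1 * ctx$larmor)
})

test_that("padding is sufficient at the default factor", {
  sh <- c(32, 32, 32)
  co <- qsmsim:::.centered_coords(grid_spec(sh, 1, 2))
  sph <- (co$x^2 + co$y^2 + co$z^2) <= 64
  ctx <- field_context()
  f2 <- simulate_iso_field(scalar_volume(0.1 * sph, grid_spec(sh, 1, 2), "ppm"), ctx)
  f4 <- simulate_iso_field(scalar_volume(0.1 * sph, grid_spec(sh, 1, 4), "ppm"), ctx)
  # masked (source-region) field changes by well under 0.5% RMS
  expect_lt(sqrt(mean((f2$values[sph] - f4$values[sph])^2)) /
              sqrt(mean(f4$values[sph]^2)), 0.005)
})

test_that("dual-echo maps recover frequency and R2* from complex signals", {
  g <- grid_spec(c(8, 8, 8), 1, 1)
  ctx <- field_context()  # TE1 = 7 ms, TE2 = 20 ms, dTE = 13 ms
  sh <- g$shape
  # phase difference 1.3 rad -> 15.915 Hz; |S2|/|S1| = e^-1 -> R2* = 76.92
  e1 <- array(complex(modulus = 1, argument = 0.2), dim = sh)
  e2 <- array(complex(modulus = exp(-1), argument = 1.5), dim = sh)
  m <- dual_echo_maps(e1, e2, g, ctx)
  expect_equal(m$frequency$values[1], 1.3 / (2 * pi * 0.013), tolerance = 1e-9)
  expect_equal(m$frequency$values[1], 15.91549, tolerance = 1e-4)
  expect_equal(m$r2star$values[1], 1 / 0.013, tolerance = 1e-9)
  # equal magnitudes give zero R2*
  e2b <- array(complex(modulus = 1, argument = 0.5), dim = sh)
  expect_equal(max(abs(dual_echo_maps(e1, e2b, g, ctx)$r2star$values)), 0)
  # zero-magnitude voxels are masked out, not made infinite
  e2c <- e2
  e2c[1, 1, 1] <- 0 + 0i
  mc <- dual_echo_maps(e1, e2c, g, ctx)
  expect_false(mc$frequency$mask[1, 1, 1])
  expect_true(all(is.finite(mc$r2star$values)))
})

test_that("tensor forward matches the real-space dipole sum outside a compact source", {
  # a small ball of uniform anisotropic tensor; the oracle sums the
  # continuum point-dipole response of every source voxel in real space.
  # (an extended source is required: the discrete kernel's Green function
  # carries voxel-scale ringing that only cancels over extended sources)
  sh <- c(24, 24, 24)
  g <- grid_spec(sh, 1, 4)
  ctx <- field_context(B0_direction = c(0.3, 0.1, 1))
  h <- ctx$B0_direction
  co <- qsmsim:::.centered_coords(g)
  ball <- (co$x^2 + co$y^2 + co$z^2) <= 2.5^2
  vals <- c(xx = 0.4, yy = -0.1, zz = 0.3, xy = 0.15, xz = -0.2, yz = 0.05)
  comps <- lapply(vals, function(v) array(v * ball, dim = sh))
  X <- symmetric_tensor_volume(comps$xx, comps$yy, comps$zz,
                               comps$xy, comps$xz, comps$yz, g)
  f <- tensor_forward(X, ctx)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  far <- which(r >= 6 & r <= 10)
  oracle <- brute_tensor_dipole_field(comps, which(ball), g, h, ctx$larmor, far)
  expect_lt(relative_rms(f$values[far], oracle), 0.1)
})
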