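test_that("multi-orientation forward matches the single-orientation model", {
  sh <- c(20, 20, 20)
  g <- grid_spec(sh, 1, 2)
  set.seed(17)
  comps <- lapply(1:6, function(i) array(rnorm(prod(sh), sd = 0.02), dim = sh))
  X <- symmetric_tensor_volume(comps[[1]], comps[[2]], comps[[3]],
                               comps[[4]], comps[[5]], comps[[6]], g)
  ors <- hemisphere_orientations(6)
  fl <- sti_forward(X, ors)
  f3 <- tensor_forward(X, field_context(B0_direction = ors[3, ]))
  expect_equal(fl[[3]]$values, f3$values, tolerance = 1e-12)
  # zero tensor gives zero fields at every orientation
  z <- symmetric_tensor_volume(array(0, sh), array(0, sh), array(0, sh),
                               array(0, sh), array(0, sh), array(0, sh), g)
  expect_true(all(vapply(sti_forward(z, ors),
                         function(v) max(abs(v$values)) == 0, logical(1))))
})

test_that("tensor inversion round-trips noise-free multi-orientation data", {
  # smooth random tensor field on a kernel-consistent grid
  sh <- c(24, 24, 24)
  g <- grid_spec(sh, 1, 1)
  set.seed(23)
  K <- qsmsim:::.kgrid(sh, g$voxel_size)
  k2 <- K$k2; k2[1] <- 0
  smooth <- function() {
    n <- array(rnorm(prod(sh)), dim = sh)
    s <- Re(stats::fft(stats::fft(n) * exp(-40 * k2), inverse = TRUE)) / prod(sh)
    0.02 * s / stats::sd(s)
  }
  comps <- replicate(6, smooth(), simplify = FALSE)
  X <- symmetric_tensor_volume(comps[[1]], comps[[2]], comps[[3]],
                               comps[[4]], comps[[5]], comps[[6]], g)
  ors <- hemisphere_orientations(12)
  f <- sti_forward(X, ors)
  Xr <- sti_invert(f, ors, params = sti_solve_params(max_iterations = 30))
  err <- den <- 0
  for (nm in names(X$components)) {
    d <- Xr$components[[nm]] - X$components[[nm]]
    d <- d - mean(d)  # the volume mean is not observable (k = 0 kernel zero)
    err <- err + sum(d^2)
    den <- den + sum(X$components[[nm]]^2)
  }
  expect_lt(sqrt(err / den), 0.05)
  # zero data gives a zero tensor
  zf <- lapply(seq_len(nrow(ors)), function(i)
    scalar_volume(array(0, dim = sh), g, "Hz"))
  Xz <- sti_invert(zf, ors)
  expect_equal(max(abs(unlist(Xz$components))), 0)
})

test_that("round-trip error decreases with iteration count on average", {
  sh <- c(16, 16, 16)
  g <- grid_spec(sh, 1, 1)
  set.seed(29)
  comps <- replicate(6, array(rnorm(prod(sh), sd = 0.02), dim = sh),
                     simplify = FALSE)
  X <- symmetric_tensor_volume(comps[[1]], comps[[2]], comps[[3]],
                               comps[[4]], comps[[5]], comps[[6]], g)
  ors <- hemisphere_orientations(10)
  f <- sti_forward(X, ors)
  errs <- vapply(c(2, 8, 30), function(it) {
    Xr <- sti_invert(f, ors, params = sti_solve_params(max_iterations = it))
    e <- d <- 0
    for (nm in names(X$components)) {
      dd <- Xr$components[[nm]] - X$components[[nm]]
      e <- e + sum((dd - mean(dd))^2); d <- d + sum(X$components[[nm]]^2)
    }
    sqrt(e / d)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("too few orientations triggers the rank warning", {
  sh <- c(12, 12, 12)
  g <- grid_spec(sh, 1, 1)
  zf <- lapply(1:4, function(i) scalar_volume(array(0, dim = sh), g, "Hz"))
  expect_warning(sti_invert(zf, hemisphere_orientations(6)[1:4, ]),
                 "fewer than 6")
})

test_that("eigen-analysis inverts the tensor construction exactly", {
  g <- grid_spec(c(8, 8, 8), 1, 1)
  sh <- g$shape
  X <- cylsym_tensor(array(-0.05, sh), array(0.0113, sh), c(0, 0, 1), g)
  ev <- tensor_eigen(X)
  expect_equal(ev$chi_iso[1], -0.05, tolerance = 1e-12)
  expect_equal(ev$chi_aniso[1], 0.0113, tolerance = 1e-7)
  expect_equal(abs(ev$pev[1, 1, 1, 3]), 1, tolerance = 1e-9)
  # eigenvalues are chi_I + chi_A (axis) and chi_I - chi_A/2 (twice);
  # the trigonometric solver carries ~1e-9 error at degenerate pairs
  expect_equal(ev$lambda1[1], -0.05 + 0.0113, tolerance = 1e-7)
  expect_equal(ev$lambda3[1], -0.05 - 0.0113 / 2, tolerance = 1e-7)
  # negative anisotropy: the most-different eigenvalue is the low one
  Xn <- cylsym_tensor(array(0.01, sh), array(-0.02, sh), c(1, 0, 0), g)
  evn <- tensor_eigen(Xn)
  expect_equal(evn$chi_aniso[1], -0.02, tolerance = 1e-7)
  expect_equal(abs(evn$pev[1, 1, 1, 1]), 1, tolerance = 1e-9)
  # isotropic voxels are degenerate: zero anisotropy, undefined pev
  Xi <- cylsym_tensor(array(0.03, sh), array(0, sh), c(0, 0, 1), g)
  evi <- tensor_eigen(Xi)
  expect_equal(evi$chi_iso[1], 0.03)
  expect_equal(evi$chi_aniso[1], 0)
  expect_true(all(evi$undefined))
  expect_true(is.na(evi$pev[1, 1, 1, 1]))
})

test_that("closed-form eigenvalues match the base eigensolver on random tensors", {
  g <- grid_spec(c(8, 8, 8), 1, 1)
  sh <- g$shape
  set.seed(41)
  comps <- replicate(6, array(rnorm(prod(sh)), dim = sh), simplify = FALSE)
  X <- symmetric_tensor_volume(comps[[1]], comps[[2]], comps[[3]],
                               comps[[4]], comps[[5]], comps[[6]], g)
  ev <- tensor_eigen(X)
  idx <- sample(prod(sh), 50)
  oracle <- eigen_oracle(X, idx)
  expect_equal(ev$lambda1[idx], oracle[, 1], tolerance = 1e-10)
  expect_equal(ev$lambda2[idx], oracle[, 2], tolerance = 1e-10)
  expect_equal(ev$lambda3[idx], oracle[, 3], tolerance = 1e-10)
  expect_equal(ev$chi_iso[idx], rowMeans(oracle), tolerance = 1e-10)
  # pev satisfies the eigen equation and has non-negative z
  i <- idx[1]
  A <- matrix(c(comps[[1]][i], comps[[4]][i], comps[[5]][i],
                comps[[4]][i], comps[[2]][i], comps[[6]][i],
                comps[[5]][i], comps[[6]][i], comps[[3]][i]), 3, 3)
  v <- c(ev$pev[, , , 1][i], ev$pev[, , , 2][i], ev$pev[, , , 3][i])
  lam <- ev$chi_iso[i] + ev$chi_aniso[i]
  expect_lt(max(abs(A %*% v - lam * v)), 1e-8)
  expect_gte(v[3], 0)
})

test_that("angle errors respect axial symmetry and exclude undefined voxels", {
  sh <- c(2, 2, 1)
  p <- array(0, dim = c(sh, 3))
  v <- array(0, dim = c(sh, 3))
  p[1, 1, 1, ] <- c(0, 0, 1);  v[1, 1, 1, ] <- c(0, 0, 1)   # identical
  p[2, 1, 1, ] <- c(0, 0, 1);  v[2, 1, 1, ] <- c(0, 0, -1)  # antiparallel
  p[1, 2, 1, ] <- c(1, 0, 0);  v[1, 2, 1, ] <- c(0, 0, 1)   # orthogonal
  p[2, 2, 1, ] <- NA;          v[2, 2, 1, ] <- c(0, 0, 1)   # undefined
  m <- array(TRUE, dim = sh)
  ae <- angle_error_map(p, v, m)
  expect_equal(ae$map[1, 1, 1], 0)
  expect_equal(ae$map[2, 1, 1], 0)
  expect_equal(ae$map[1, 2, 1], 90)
  expect_equal(ae$n, 3)
  expect_equal(ae$n_undefined, 1)
  expect_equal(ae$mean, 30)
})

test_that("compact tensor source field matches the real-space dipole sum", {
  sh <- c(24, 24, 24)
  g <- grid_spec(sh, 1, 4)
  ctx <- field_context(B0_direction = c(0, 0.2, 1))
  co <- qsmsim:::.centered_coords(g)
  ball <- (co$x^2 + co$y^2 + co$z^2) <= 2.5^2
  vals <- c(xx = -0.2, yy = 0.5, zz = 0.1, xy = 0.1, xz = 0.05, yz = -0.15)
  comps <- lapply(vals, function(v) array(v * ball, dim = sh))
  X <- symmetric_tensor_volume(comps$xx, comps$yy, comps$zz,
                               comps$xy, comps$xz, comps$yz, g)
  f <- sti_forward(X, matrix(ctx$B0_direction, nrow = 1))[[1]]
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  far <- which(r >= 6 & r <= 10)
  oracle <- brute_tensor_dipole_field(comps, which(ball), g,
                                      ctx$B0_direction, ctx$larmor, far)
  expect_lt(relative_rms(f$values[far], oracle), 0.1)
})
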