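#' The ten acquisition angles of the nerve-rotation experiment
#'
#' Angles between the nerve axis and B0: 0 to 90 degrees in even steps of
#' 10 degrees (first acquisition parallel, last perpendicular).
#'
#' @return numeric vector of length 10.
#' @export
ten_orientation_angles <- function() seq(0, 90, by = 10)

#' Quasi-uniform unit directions on the upper hemisphere
#'
#' Deterministic Fibonacci-spiral construction of `n` unit vectors with
#' non-negative z, emulating B0 directions spread evenly over a
#' hemispherical surface for tensor imaging.
#'
#' @param n number of directions (>= 6 for a solvable tensor inversion).
#' @param seed accepted for interface symmetry with the other generators;
#'   the construction is deterministic and ignores it.
#' @return `n x 3` matrix of unit row vectors, `v[, 3] >= 0`.
#' @export
hemisphere_orientations <- function(n = 16, seed = NULL) {
  if (n < 6) stop("need at least 6 orientations for tensor inversion")
  i <- seq_len(n)
  z <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Add seeded Gaussian noise to a volume
#'
#' @param vol a [scalar_volume()].
#' @param sd noise standard deviation in the volume's units (>= 0).
#' @param seed optional integer; when given, the RNG state is saved,
#'   seeded, and restored, so the call is reproducible and side-effect
#'   free.
#' @return A [scalar_volume()].
#' @export
add_noise <- function(vol, sd, seed = NULL) {
  if (sd < 0) stop("'sd' must be >= 0")
  if (sd == 0) return(vol)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  v <- vol$values + array(stats::rnorm(length(vol$values), sd = sd),
                          dim = dim(vol$values))
  scalar_volume(v, vol$grid, vol$units, mask = vol$mask)
}

#' Specification of the synthetic nerve-in-sphere phantom
#'
#' A cylindrical white-matter (optic nerve) sample embedded in an agarose
#' gel sphere and imaged at several angles to B0. Defaults reproduce the
#' study conditions: bulk susceptibilities from the optic-nerve fit
#' (chi_I = -0.08152 ppm, chi_A = 0.01128 ppm relative to the gel),
#' residual-offset model coefficients A = -5.59 Hz and b = 4.88 Hz, ten
#' angles from 0 to 90 degrees, 0.5 mm voxels, and no noise. The sphere is
#' scaled down from the 10 cm experimental vessel so that the phantom fits
#' a 64^3 grid while keeping the nerve dimensions and voxel size.
#'
#' @param sphere_radius gel sphere radius, mm.
#' @param nerve_radius,nerve_length nerve cylinder radius and full length, mm.
#' @param chiI_true,chiA_true bulk susceptibilities of the nerve relative
#'   to the gel, ppm.
#' @param residual_A,residual_b injected internal residual-offset model
#'   coefficients, Hz (`A sin^2(theta) + b` inside the eroded nerve).
#' @param angles acquisition angles between nerve axis and B0, degrees.
#' @param noise_sd Gaussian frequency noise SD, Hz (0 = noise free).
#' @param seed integer seed for noise and bubble placement.
#' @param grid a [grid_spec()]; default 64^3 at 0.5 mm, pad factor 2.
#' @param r2star_gel,r2star_nerve R2* assigned to gel and nerve, s^-1.
#' @param n_bubbles number of simulated air-bubble markers in the gel
#'   (voxels with R2* above the exclusion threshold, for testing the
#'   R2*-based voxel qualification; they carry no field perturbation).
#' @return An object of class `nerve_phantom_spec`.
#' @export
nerve_phantom_spec <- function(sphere_radius = 15, nerve_radius = 2,
                               nerve_length = 16,
                               chiI_true = -0.08152, chiA_true = 0.01128,
                               residual_A = -5.59, residual_b = 4.88,
                               angles = ten_orientation_angles(),
                               noise_sd = 0, seed = 1,
                               grid = grid_spec(c(64, 64, 64), 0.5, 2),
                               r2star_gel = 5, r2star_nerve = 25,
                               n_bubbles = 3) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (any(angles < 0 | angles > 90)) stop("angles must lie in [0, 90] degrees")
  if (sqrt(nerve_radius^2 + (nerve_length / 2)^2) >= sphere_radius)
    stop("nerve does not fit inside the sphere")
  structure(list(sphere_radius = sphere_radius, nerve_radius = nerve_radius,
                 nerve_length = nerve_length, chiI_true = chiI_true,
                 chiA_true = chiA_true, residual_A = residual_A,
                 residual_b = residual_b, angles = angles,
                 noise_sd = noise_sd, seed = seed, grid = grid,
                 r2star_gel = r2star_gel, r2star_nerve = r2star_nerve,
                 n_bubbles = n_bubbles),
            class = "nerve_phantom_spec")
}

# centred physical coordinates (mm) of a grid
.centered_coords <- function(grid) {
  sh <- grid$shape; vs <- grid$voxel_size
  cx <- (seq_len(sh[1]) - (sh[1] + 1) / 2) * vs[1]
  cy <- (seq_len(sh[2]) - (sh[2] + 1) / 2) * vs[2]
  cz <- (seq_len(sh[3]) - (sh[3] + 1) / 2) * vs[3]
  list(x = array(cx, dim = sh),
       y = array(rep(cy, each = sh[1]), dim = sh),
       z = array(rep(cz, each = sh[1] * sh[2]), dim = sh))
}

#' Generate the synthetic nerve-in-sphere phantom
#'
#' For each acquisition angle theta the B0 direction is rotated in the
#' x-z plane of the fixed sample frame (the nerve axis stays along z,
#' matching coregistration of all acquisitions to a common sample space).
#' Per orientation the generator simulates the unit-response fields `F_I`
#' and `F_A` (Hz per ppm) from the nerve mask, composes the true field
#' `chi_I F_I + chi_A F_A`, injects the internal residual offset
#' `A sin^2(theta) + b` uniformly inside the nerve mask eroded by one
#' voxel, and adds seeded Gaussian noise. A matched R2* volume is emitted
#' (low in gel, high in nerve, optional bubble markers above the
#' qualification threshold).
#'
#' @param spec a [nerve_phantom_spec()].
#' @return An object of class `nerve_phantom`: grid, masks (`nerve_mask`,
#'   `sphere_mask`, `residual_region`), `angles`, `b0_dirs` (one row per
#'   orientation), per-orientation lists `f_meas`, `f_true`, `unit_iso`,
#'   `unit_aniso` (scalar volumes), `r2star`, and the generating `spec`.
#' @export
make_nerve_phantom <- function(spec = nerve_phantom_spec()) {
  g <- spec$grid
  co <- .centered_coords(g)
  sphere <- (co$x^2 + co$y^2 + co$z^2) <= spec$sphere_radius^2
  nerve <- (co$x^2 + co$y^2) <= spec$nerve_radius^2 &
    abs(co$z) <= spec$nerve_length / 2
  if (any(nerve & !sphere)) stop("nerve is not contained in the sphere")
  resid_region <- erode_mask(nerve, 1)
  if (!any(resid_region)) stop("nerve too thin: 1-voxel erosion empties it")

  psh <- .padded_shape(g)
  Mhat <- stats::fft(.pad_array(array(as.numeric(nerve), dim = g$shape), psh))
  f0 <- larmor_scale(7)

  n_or <- length(spec$angles)
  b0_dirs <- t(vapply(spec$angles, polar_axis, numeric(3)))
  unit_iso <- unit_aniso <- f_true <- f_meas <- vector("list", n_or)

  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
  }

  for (i in seq_len(n_or)) {
    h <- b0_dirs[i, ]
    D <- .iso_kernel_arr(psh, g$voxel_size, h)
    A <- .cylsym_kernel_arr(psh, g$voxel_size, c(0, 0, 1), h)
    FI <- f0 * .crop_array(.ifft_re(Mhat * D), g$shape)
    FA <- f0 * .crop_array(.ifft_re(Mhat * A), g$shape)
    ft <- spec$chiI_true * FI + spec$chiA_true * FA
    th <- spec$angles[i] * pi / 180
    fm <- ft + (spec$residual_A * sin(th)^2 + spec$residual_b) * resid_region
    if (spec$noise_sd > 0)
      fm <- fm + array(stats::rnorm(length(fm), sd = spec$noise_sd), dim = dim(fm))
    unit_iso[[i]] <- scalar_volume(FI, g, "Hz", mask = sphere)
    unit_aniso[[i]] <- scalar_volume(FA, g, "Hz", mask = sphere)
    f_true[[i]] <- scalar_volume(ft, g, "Hz", mask = sphere)
    f_meas[[i]] <- scalar_volume(fm, g, "Hz", mask = sphere)
  }

  r2s <- array(0, dim = g$shape)
  r2s[sphere] <- spec$r2star_gel
  r2s[nerve] <- spec$r2star_nerve
  if (spec$n_bubbles > 0) {
    gel_far <- sphere & !dilate_mask(nerve, 10) & erode_mask(sphere, 6)
    idx <- which(gel_far)
    if (length(idx) >= spec$n_bubbles) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(spec$seed + 1L)
      pick <- sample(idx, spec$n_bubbles)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
      bub <- array(FALSE, dim = g$shape)
      bub[pick] <- TRUE
      r2s[dilate_mask(bub, 1)] <- 40
    }
  }

  structure(list(spec = spec, grid = g, nerve_mask = nerve,
                 sphere_mask = sphere, residual_region = resid_region,
                 angles = spec$angles, b0_dirs = b0_dirs,
                 f_meas = f_meas, f_true = f_true,
                 unit_iso = unit_iso, unit_aniso = unit_aniso,
                 r2star = scalar_volume(r2s, g, "s^-1", mask = sphere)),
            class = "nerve_phantom")
}

#' Generate the synthetic digital brain susceptibility model
#'
#' A geometric whole-brain model carrying everything the frequency
#' composer needs: an ellipsoidal brain mask; a white-matter (WM) interior
#' with a smooth fiber-orientation unit-vector field built from three
#' parametric tract systems (a left-right arch emulating the corpus
#' callosum, bilateral inferior-superior bundles emulating the internal
#' capsule / corticospinal tract, and bilateral anterior-posterior bundles
#' emulating the optic radiations); an FA map high on tract cores and
#' decaying outward, with a smooth seeded texture; deep grey-matter
#' ellipsoids (globus pallidus, putamen, caudate, thalamus, pulvinar) with
#' fixed isotropic susceptibilities; `chi_I = -0.05 ppm` in WM and 0 in
#' CSF/cortical GM; and `chi_A = 0.0113 ppm x FA/0.59` in WM (zero inside
#' the deep-GM structures).
#'
#' @param grid a [grid_spec()]; default 64^3 at 3 mm with `pad_factor = 1`
#'   (kernel-consistent simulation/inversion).
#' @param seed integer seed for the FA texture.
#' @param chiA_wm anisotropy parameter assigned at the reference FA, ppm.
#' @param chiI_wm isotropic WM offset relative to non-WM, ppm.
#' @param fa_ref FA normalization constant (in vivo optic-nerve FA).
#' @return An object of class `brain_model`: `chiI`, `chiA`
#'   ([scalar_volume()]s, ppm), `fiber_dirs` (array `c(shape, 3)`, unit
#'   vectors in WM), `FA` (scalar_volume), `wm_mask`, `deep_gm_masks`
#'   (named list with `chi` values as an attribute), `brain_mask`,
#'   `ventricle_mask`, `rois` (coherent-fiber ROIs on the tract cores:
#'   `CC`, `IC`, `OR`), `grid`.
#' @export
make_brain_model <- function(grid = grid_spec(c(64, 64, 64), 3, 1), seed = 1,
                             chiA_wm = 0.0113, chiI_wm = -0.05,
                             fa_ref = 0.59) {
  co <- .centered_coords(grid)
  sh <- grid$shape
  ell <- function(cen, semi)
    ((co$x - cen[1]) / semi[1])^2 + ((co$y - cen[2]) / semi[2])^2 +
    ((co$z - cen[3]) / semi[3])^2 <= 1
  fov <- sh * grid$voxel_size
  sc <- min(fov) / 192  # geometry authored at a 192 mm field of view
  brain <- ell(c(0, 0, 0), sc * c(75, 85, 65))
  wm_all <- ell(c(0, 0, 0), sc * c(55, 65, 45))
  # lateral ventricles: CSF, carved out of the WM interior
  ventricles <- (ell(sc * c(8, 12, 6), sc * c(5, 22, 7)) |
                   ell(sc * c(-8, 12, 6), sc * c(5, 22, 7))) & brain

  # deep grey structures; the pulvinar is defined before the thalamus so
  # the posterior thalamic region keeps its own susceptibility, and later
  # masks never overwrite earlier ones
  gm_def <- list(
    GP = list(cen = c(18, 0, 0), semi = c(6, 10, 6), chi = 0.15),
    PU = list(cen = c(27, 4, 0), semi = c(7, 12, 7), chi = 0.05),
    CN = list(cen = c(12, 26, 6), semi = c(5, 10, 6), chi = 0.05),
    PV = list(cen = c(14, -24, 2), semi = c(5, 6, 5), chi = 0.03),
    TH = list(cen = c(12, -14, 2), semi = c(9, 11, 8), chi = 0.00))
  deep_gm <- list()
  gm_chi <- numeric(0)
  taken <- ventricles
  for (nm in names(gm_def)) {
    d <- gm_def[[nm]]
    m <- ell(sc * d$cen, sc * d$semi) | ell(sc * c(-d$cen[1], d$cen[2], d$cen[3]),
                                            sc * d$semi)
    m <- m & brain & !taken
    taken <- taken | m
    deep_gm[[nm]] <- m
    gm_chi[nm] <- d$chi
  }
  gm_any <- Reduce(`|`, deep_gm)

  # convoluted WM boundary: a smooth seeded random field carves gyral
  # non-WM tissue into the outer half of the WM compartment, emulating
  # the WM/GM interface heterogeneity of a real segmentation
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  noise1 <- array(stats::rnorm(prod(sh)), dim = sh)
  noise2 <- array(stats::rnorm(prod(sh)), dim = sh)
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  K <- .kgrid(sh, grid$voxel_size)
  k2 <- K$k2; k2[1] <- 0
  smooth_of <- function(noise, len_mm) {
    s <- .ifft_re(stats::fft(noise) * exp(-2 * pi^2 * len_mm^2 * k2))
    s / max(stats::sd(s), 1e-12)
  }
  carve <- smooth_of(noise1, 9)
  rim <- ell(c(0, 0, 0), sc * c(55, 65, 45)) &
    !ell(c(0, 0, 0), sc * c(38, 46, 31))
  wm <- wm_all & !gm_any & !ventricles & !(rim & carve > 0.1)

  # --- tract primitives: core distance d_i (mm) and tangent field t_i ---
  x <- co$x / sc; y <- co$y / sc; z <- co$z / sc  # authoring frame, mm
  # 1. corpus callosum: left-right arch in the x-z plane
  zc <- -8; yc <- 8; Rarc <- 28
  rho <- sqrt(x^2 + (z - zc)^2)
  d1 <- sqrt((rho - Rarc)^2 + (y - yc)^2)
  d1[z < zc] <- d1[z < zc] + (zc - z[z < zc])  # arch only above its centre
  rho_s <- pmax(rho, 1e-6)
  t1x <- (z - zc) / rho_s; t1y <- 0 * x; t1z <- -x / rho_s
  # 2. internal capsule / corticospinal: bilateral vertical bundles
  d2 <- sqrt((abs(x) - 20)^2 + (y + 5)^2)
  t2x <- 0.2 * sign(x) * z / 60; t2y <- 0 * x; t2z <- 1 + 0 * x
  # 3. optic radiations: bilateral anterior-posterior bundles, posterior
  d3 <- sqrt((abs(x) - 25)^2 + z^2) + pmax(0, y + 10) / 2
  t3x <- 0 * x; t3y <- 1 + 0 * x; t3z <- 0 * x

  sig <- 10
  w1 <- exp(-(d1 / sig)^2); w2 <- exp(-(d2 / sig)^2); w3 <- exp(-(d3 / sig)^2)
  vx <- w1 * t1x + w2 * t2x + w3 * t3x
  vy <- w1 * t1y + w2 * t2y + w3 * t3y
  vz <- w1 * t1z + w2 * t2z + w3 * t3z
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  flat <- nrm < 1e-8
  vx[flat] <- 1; vy[flat] <- 0; vz[flat] <- 0
  nrm[flat] <- 1
  vx <- vx / nrm; vy <- vy / nrm; vz <- vz / nrm

  # FA: high on tract cores, decaying outward, plus a smooth seeded texture
  dmin <- pmin(d1, d2, d3)
  fa <- 0.2 + 0.68 * exp(-(dmin / 10)^2)
  fa <- array(pmin(1, pmax(0, fa + 0.05 * smooth_of(noise2, 6))), dim = sh)
  fa[!wm] <- 0

  fiber <- array(0, dim = c(sh, 3L))
  fiber[, , , 1] <- vx * wm
  fiber[, , , 2] <- vy * wm
  fiber[, , , 3] <- vz * wm

  chiI <- array(0, dim = sh)
  chiI[wm] <- chiI_wm
  for (nm in names(deep_gm)) chiI[deep_gm[[nm]]] <- gm_chi[nm]
  chiA <- array(0, dim = sh)
  chiA[wm] <- chiA_wm * fa[wm] / fa_ref

  attr(deep_gm, "chi") <- gm_chi
  structure(list(
    chiI = scalar_volume(chiI, grid, "ppm", mask = brain),
    chiA = scalar_volume(chiA, grid, "ppm", mask = brain),
    fiber_dirs = fiber,
    FA = scalar_volume(fa, grid, "dimensionless", mask = brain),
    wm_mask = wm, deep_gm_masks = deep_gm, brain_mask = brain,
    ventricle_mask = ventricles,
    rois = list(CC = wm & d1 <= 5, IC = wm & d2 <= 5, OR = wm & d3 <= 5),
    grid = grid),
    class = "brain_model")
}
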