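#' STI solver parameters
#'
#' @param max_iterations conjugate-gradient iteration cap (default 30,
#'   which normally dominates over the tolerance).
#' @param tolerance relative residual of the normal equations at which
#'   iteration stops early (default 1e-6).
#' @return An object of class `sti_solve_params`.
#' @export
sti_solve_params <- function(max_iterations = 30, tolerance = 1e-6) {
  if (max_iterations < 1) stop("'max_iterations' must be >= 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "sti_solve_params")
}

#' Multi-orientation tensor forward model
#'
#' Evaluates [tensor_forward()] for each B0 direction in `orientations`,
#' factoring the Fourier transforms of the six tensor components out of
#' the orientation loop.
#'
#' @param X a [symmetric_tensor_volume()].
#' @param orientations matrix of unit B0 row vectors.
#' @param B0_strength tesla.
#' @param mask optional logical array attached to the outputs.
#' @return list of [scalar_volume()]s in Hz, one per orientation.
#' @export
sti_forward <- function(X, orientations, B0_strength = 7, mask = NULL) {
  if (!inherits(X, "symmetric_tensor_volume"))
    stop("'X' must be a symmetric_tensor_volume")
  if (is.null(dim(orientations))) orientations <- matrix(orientations, nrow = 1)
  g <- X$grid
  psh <- .padded_shape(g)
  f0 <- larmor_scale(B0_strength)
  Xhat <- lapply(X$components, function(v) stats::fft(.pad_array(v, psh)))
  out <- vector("list", nrow(orientations))
  for (i in seq_len(nrow(orientations))) {
    h <- orientations[i, ]
    h <- h / sqrt(sum(h^2))
    coeff <- .tensor_coeff_arrs(psh, g$voxel_size, h)
    acc <- array(0 + 0i, dim = psh)
    for (nm in names(coeff)) acc <- acc + coeff[[nm]] * Xhat[[nm]]
    out[[i]] <- scalar_volume(f0 * .crop_array(.ifft_re(acc), g$shape),
                              g, "Hz", mask = mask)
  }
  out
}

#' Susceptibility tensor inversion by conjugate gradients
#'
#' Least-squares solution of the stacked linear system relating the six
#' k-space tensor-component spectra to the measured frequency maps over
#' all orientations, solved by conjugate-gradient iteration on the normal
#' equations (CGNR) with a hard iteration cap. No regularization term is
#' added; inversion is kernel-consistent on the acquisition grid (no
#' padding).
#'
#' When the frequency volumes carry a mask (brain-masked data, where no
#' frequency information exists outside the head), the data-fidelity term
#' is restricted to the masked voxels: the forward operator becomes
#' mask-then-compare in image space, which couples k-space cells and makes
#' the solve an iterative (rather than pointwise) problem — this is the
#' operator the iteration cap matters for. Unmasked volumes use the pure
#' k-space system, which decouples per k-cell and converges quickly.
#'
#' @param freqs list of [scalar_volume()]s in Hz, one per orientation.
#'   If the first volume has a mask, masked least squares is used.
#' @param orientations matrix of unit B0 row vectors matching `freqs`.
#' @param B0_strength tesla.
#' @param params a [sti_solve_params()].
#' @return A [symmetric_tensor_volume()] in ppm, with attribute
#'   `solver_info` (iterations run, final relative residual of the normal
#'   equations, whether the masked operator was used, and whether fewer
#'   than 6 orientations forced a best-effort rank-deficient solve).
#' @export
sti_invert <- function(freqs, orientations, B0_strength = 7,
                       params = sti_solve_params()) {
  if (is.null(dim(orientations))) orientations <- matrix(orientations, nrow = 1)
  n_or <- length(freqs)
  if (nrow(orientations) != n_or)
    stop("one orientation per frequency map required")
  rank_warn <- n_or < 6L
  if (rank_warn)
    warning("fewer than 6 orientations: tensor solve is rank deficient; ",
            "returning the minimum-norm CG iterate")
  g <- freqs[[1]]$grid
  sh <- g$shape
  f0 <- larmor_scale(B0_strength)

  mask <- freqs[[1]]$mask
  masked <- !is.null(mask)

  coeffs <- vector("list", n_or)
  fhat <- vector("list", n_or)
  for (o in seq_len(n_or)) {
    if (freqs[[o]]$units != "Hz") stop("frequency maps must be in Hz")
    if (!all(freqs[[o]]$grid$shape == sh)) stop("frequency maps on different grids")
    h <- orientations[o, ]
    coeffs[[o]] <- .tensor_coeff_arrs(sh, g$voxel_size, h / sqrt(sum(h^2)))
    v <- freqs[[o]]$values / f0
    if (masked) v[!mask] <- 0
    fhat[[o]] <- stats::fft(v)
  }
  cn <- names(coeffs[[1]])
  N <- prod(sh)

  if (masked) {
    # data term restricted to the mask: A x = FT{ M . IFT(sum_c a_c x_c) }
    A_apply <- function(x) lapply(seq_len(n_or), function(o) {
      acc <- array(0 + 0i, dim = sh)
      for (c6 in cn) acc <- acc + coeffs[[o]][[c6]] * x[[c6]]
      v <- stats::fft(acc, inverse = TRUE) / N
      v[!mask] <- 0
      stats::fft(v)
    })
    At_apply <- function(r) {
      rm_ <- lapply(r, function(z) {
        v <- stats::fft(z, inverse = TRUE) / N
        v[!mask] <- 0
        stats::fft(v)
      })
      out <- stats::setNames(vector("list", 6L), cn)
      for (c6 in cn) {
        acc <- array(0 + 0i, dim = sh)
        for (o in seq_len(n_or)) acc <- acc + coeffs[[o]][[c6]] * rm_[[o]]
        out[[c6]] <- acc
      }
      out
    }
  } else {
    A_apply <- function(x) lapply(seq_len(n_or), function(o) {
      acc <- array(0 + 0i, dim = sh)
      for (c6 in cn) acc <- acc + coeffs[[o]][[c6]] * x[[c6]]
      acc
    })
    At_apply <- function(r) {
      out <- stats::setNames(vector("list", 6L), cn)
      for (c6 in cn) {
        acc <- array(0 + 0i, dim = sh)
        for (o in seq_len(n_or)) acc <- acc + coeffs[[o]][[c6]] * r[[o]]
        out[[c6]] <- acc
      }
      out
    }
  }
  ip <- function(a, b) sum(vapply(seq_along(a),
                                  function(i) Re(sum(Conj(a[[i]]) * b[[i]])),
                                  numeric(1)))

  b <- At_apply(fhat)
  x <- lapply(b, function(z) array(0 + 0i, dim = sh))
  r <- b
  p <- r
  rs <- ip(r, r)
  b_norm <- sqrt(rs)
  iters <- 0L
  rel <- 1
  if (b_norm > 0) {
    for (it in seq_len(params$max_iterations)) {
      q <- At_apply(A_apply(p))
      pq <- ip(p, q)
      if (pq <= 0) break
      alpha <- rs / pq
      for (c6 in cn) {
        x[[c6]] <- x[[c6]] + alpha * p[[c6]]
        r[[c6]] <- r[[c6]] - alpha * q[[c6]]
      }
      rs_new <- ip(r, r)
      iters <- it
      rel <- sqrt(rs_new) / b_norm
      if (rel < params$tolerance) break
      beta <- rs_new / rs
      rs <- rs_new
      for (c6 in cn) p[[c6]] <- r[[c6]] + beta * p[[c6]]
    }
  } else {
    rel <- 0
  }
  comp <- lapply(x, function(z) Re(stats::fft(z, inverse = TRUE)) / length(z))
  out <- symmetric_tensor_volume(comp$xx, comp$yy, comp$zz,
                                 comp$xy, comp$xz, comp$yz, g)
  attr(out, "solver_info") <- list(iterations = iters, rel_residual = rel,
                                   masked = masked,
                                   rank_deficient = rank_warn)
  out
}

#' Voxelwise eigen-analysis of a tensor field
#'
#' Closed-form eigendecomposition of each voxel's symmetric 3x3 tensor
#' (trigonometric solution of the characteristic polynomial). Derived
#' maps: `chi_iso` = mean eigenvalue; `lambda_dif` = the eigenvalue with
#' the largest difference from the mean; `chi_aniso = lambda_dif -
#' chi_iso` (this convention returns exactly the generating `chi_A` for
#' tensors built as `chi_I I + chi_A (3/2)(nn^T - I/3)`); `pev` = the
#' eigenvector of `lambda_dif`, sign-normalized to non-negative z — the
#' tensor-based fiber-direction estimate. Degenerate (isotropic) voxels
#' get `chi_aniso = 0` and an undefined (NA) pev, and are flagged.
#'
#' @param X a [symmetric_tensor_volume()].
#' @param mask optional logical array restricting the analysis (voxels
#'   outside get zeros / NA pev).
#' @param degenerate_tol relative anisotropy below which a voxel is
#'   treated as isotropic.
#' @return An object of class `tensor_eigen`: arrays `lambda1` >=
#'   `lambda2` >= `lambda3`, `chi_iso`, `chi_aniso`, `pev` (dim
#'   `c(shape, 3)`), logical `undefined`, and the grid.
#' @export
tensor_eigen <- function(X, mask = NULL, degenerate_tol = 1e-12) {
  sh <- X$grid$shape
  idx <- if (is.null(mask)) seq_len(prod(sh)) else which(mask != 0)
  cm <- X$components
  xx <- cm$xx[idx]; yy <- cm$yy[idx]; zz <- cm$zz[idx]
  xy <- cm$xy[idx]; xz <- cm$xz[idx]; yz <- cm$yz[idx]

  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  scale <- pmax(abs(xx), abs(yy), abs(zz), abs(xy), abs(xz), abs(yz), abs(q))
  degen <- sqrt(p2) <= degenerate_tol * pmax(scale, 1e-300) | p2 == 0
  p <- sqrt(pmax(p2, 1e-300) / 6)
  # B = (A - q I)/p; r = det(B)/2 in [-1, 1]
  bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
  bxy <- xy / p; bxz <- xz / p; byz <- yz / p
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  rr <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(rr) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[degen] <- q[degen]; l2[degen] <- q[degen]; l3[degen] <- q[degen]

  use_l1 <- (l1 - q) >= (q - l3)
  ldif <- ifelse(use_l1, l1, l3)
  chiA <- ldif - q
  chiA[degen] <- 0

  # eigenvector of ldif: cross products of rows of (A - ldif I)
  r1x <- xx - ldif; r1y <- xy; r1z <- xz
  r2x <- xy; r2y <- yy - ldif; r2z <- yz
  r3x <- xz; r3y <- yz; r3z <- zz - ldif
  cr <- function(ax, ay, az, bx, by, bz)
    list(x = ay * bz - az * by, y = az * bx - ax * bz, z = ax * by - ay * bx)
  c12 <- cr(r1x, r1y, r1z, r2x, r2y, r2z)
  c13 <- cr(r1x, r1y, r1z, r3x, r3y, r3z)
  c23 <- cr(r2x, r2y, r2z, r3x, r3y, r3z)
  n12 <- c12$x^2 + c12$y^2 + c12$z^2
  n13 <- c13$x^2 + c13$y^2 + c13$z^2
  n23 <- c23$x^2 + c23$y^2 + c23$z^2
  best <- pmax(n12, n13, n23)
  vx <- ifelse(n12 == best, c12$x, ifelse(n13 == best, c13$x, c23$x))
  vy <- ifelse(n12 == best, c12$y, ifelse(n13 == best, c13$y, c23$y))
  vz <- ifelse(n12 == best, c12$z, ifelse(n13 == best, c13$z, c23$z))
  nv <- sqrt(best)
  undef <- degen | nv <= degenerate_tol * pmax(scale^2, 1e-300)
  nv[nv == 0] <- 1
  vx <- vx / nv; vy <- vy / nv; vz <- vz / nv
  flip <- vz < 0 | (vz == 0 & vy < 0) | (vz == 0 & vy == 0 & vx < 0)
  vx[flip] <- -vx[flip]; vy[flip] <- -vy[flip]; vz[flip] <- -vz[flip]
  vx[undef] <- NA; vy[undef] <- NA; vz[undef] <- NA

  put <- function(v, fill = 0) {
    a <- array(fill, dim = sh)
    a[idx] <- v
    a
  }
  pev <- array(NA_real_, dim = c(sh, 3L))
  pev[, , , 1][idx] <- vx
  pev[, , , 2][idx] <- vy
  pev[, , , 3][idx] <- vz
  structure(list(lambda1 = put(l1), lambda2 = put(l2), lambda3 = put(l3),
                 chi_iso = put(q), chi_aniso = put(chiA), pev = pev,
                 undefined = put(undef, fill = FALSE) != 0,
                 grid = X$grid),
            class = "tensor_eigen")
}

#' Angular error between estimated and true fiber axes
#'
#' `arccos |p . v|` per voxel in degrees (axial quantities: antiparallel
#' vectors have zero error). Voxels with an undefined estimate are
#' excluded and counted.
#'
#' @param pev array `c(shape, 3)` of estimated axes (NA where undefined).
#' @param truth_dirs array `c(shape, 3)` of true axes.
#' @param mask 3D logical array over which to summarize.
#' @return list: `map` (3D array of degrees, NA outside mask/undefined),
#'   `mean`, `sd` (population), `n`, `n_undefined`.
#' @export
angle_error_map <- function(pev, truth_dirs, mask) {
  sh <- dim(pev)[1:3]
  comp <- function(a, i) array(a[, , , i], dim = sh)
  px <- comp(pev, 1); py <- comp(pev, 2); pz <- comp(pev, 3)
  tx <- comp(truth_dirs, 1); ty <- comp(truth_dirs, 2); tz <- comp(truth_dirs, 3)
  dot <- px * tx + py * ty + pz * tz
  np <- sqrt(px^2 + py^2 + pz^2)
  nt <- sqrt(tx^2 + ty^2 + tz^2)
  ang <- array(acos(pmin(1, abs(dot) / pmax(np * nt, 1e-300))) * 180 / pi,
               dim = sh)
  ang[!mask] <- NA
  ok <- mask & !is.na(ang) & nt > 1e-12
  v <- ang[ok]
  list(map = ifelse(is.na(ang), NA, ang),
       mean = mean(v), sd = sqrt(mean((v - mean(v))^2)),
       n = sum(ok), n_undefined = sum(mask & !ok))
}
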