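# Internal Fourier helpers shared by the forward models, SHARP and the
# inversion routines. All k coordinates are in cycles/mm; only direction
# ratios enter the dipole kernels, but physical units keep anisotropic
# voxels correct.

.fftfreq <- function(n, d = 1) {
  c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L)) / (n * d)
}

# k-coordinate arrays for a given array shape + voxel size
.kgrid <- function(shape, voxel_size) {
  fx <- .fftfreq(shape[1], voxel_size[1])
  fy <- .fftfreq(shape[2], voxel_size[2])
  fz <- .fftfreq(shape[3], voxel_size[3])
  kx <- array(fx, dim = shape)
  ky <- array(rep(fy, each = shape[1]), dim = shape)
  kz <- array(rep(fz, each = shape[1] * shape[2]), dim = shape)
  k2 <- kx^2 + ky^2 + kz^2
  k2[1] <- Inf  # k = 0: kernels are defined to vanish there
  list(kx = kx, ky = ky, kz = kz, k2 = k2)
}

.pad_array <- function(a, pshape) {
  sh <- dim(a)
  if (all(sh == pshape)) return(a)
  out <- array(0, dim = pshape)
  out[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])] <- a
  out
}

.crop_array <- function(a, shape) {
  if (all(dim(a) == shape)) return(a)
  a[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])]
}

.ifft_re <- function(A) Re(stats::fft(A, inverse = TRUE)) / length(A)

# Isotropic dipole kernel D(k) = 1/3 - (k.h)^2/|k|^2, D(0) = 0
.iso_kernel_arr <- function(shape, voxel_size, h) {
  K <- .kgrid(shape, voxel_size)
  kd <- K$kx * h[1] + K$ky * h[2] + K$kz * h[3]
  D <- 1 / 3 - kd^2 / K$k2
  D[1] <- 0
  D
}

# Anisotropic kernel for a uniform-axis, zero-trace, cylindrically
# symmetric unit tensor (3/2)(n n^T - I/3):
#   A(k) = (1/2)((n.h)^2 - 1/3) - (3/2)(k.h)((k.n)(n.h) - (k.h)/3)/|k|^2
.cylsym_kernel_arr <- function(shape, voxel_size, n, h) {
  K <- .kgrid(shape, voxel_size)
  kd <- K$kx * h[1] + K$ky * h[2] + K$kz * h[3]
  kn <- K$kx * n[1] + K$ky * n[2] + K$kz * n[3]
  nh <- sum(n * h)
  A <- 0.5 * (nh^2 - 1 / 3) - 1.5 * kd * (kn * nh - kd / 3) / K$k2
  A[1] <- 0
  A
}

# Per-component coefficient arrays of the general tensor forward model:
# fhat/f0 = sum_c a_c(k) Xhat_c(k), components ordered xx,yy,zz,xy,xz,yz.
# a_ii = h_i^2/3 - (k.h) k_i h_i / |k|^2
# a_ij = 2 h_i h_j/3 - (k.h)(k_i h_j + k_j h_i)/|k|^2   (i < j)
# The k = 0 term of every coefficient is set to 0.
.tensor_coeff_arrs <- function(shape, voxel_size, h) {
  K <- .kgrid(shape, voxel_size)
  kd <- K$kx * h[1] + K$ky * h[2] + K$kz * h[3]
  r <- kd / K$k2
  kk <- list(K$kx, K$ky, K$kz)
  out <- vector("list", 6L)
  names(out) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  idx <- list(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (c6 in seq_len(6L)) {
    i <- idx[[c6]][1]; j <- idx[[c6]][2]
    if (i == j) {
      a <- h[i]^2 / 3 - r * kk[[i]] * h[i]
    } else {
      a <- 2 * h[i] * h[j] / 3 - r * (kk[[i]] * h[j] + kk[[j]] * h[i])
    }
    a[1] <- 0
    out[[c6]] <- a
  }
  out
}

# Wrapped (origin-centred) spherical kernel of given radius in voxels,
# normalized to unit sum; used by SHARP and as a morphology structuring
# element through its k-space form.
.sphere_kernel_arr <- function(shape, radius_vox) {
  ix <- function(n) {
    v <- seq_len(n) - 1L
    v[v > n / 2] <- v[v > n / 2] - n
    v
  }
  dx <- array(ix(shape[1]), dim = shape)
  dy <- array(rep(ix(shape[2]), each = shape[1]), dim = shape)
  dz <- array(rep(ix(shape[3]), each = shape[1] * shape[2]), dim = shape)
  ker <- (dx^2 + dy^2 + dz^2) <= radius_vox^2 + 1e-9
  ker / sum(ker)
}
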