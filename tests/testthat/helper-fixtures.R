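# Shared fixtures and independent oracles used across the test files.

# brute-force binary dilation with a Euclidean ball (loop over offsets)
brute_dilate <- function(mask, r) {
  sh <- dim(mask)
  out <- array(FALSE, dim = sh)
  rr <- ceiling(r)
  idx <- which(mask, arr.ind = TRUE)
  for (dx in -rr:rr) for (dy in -rr:rr) for (dz in -rr:rr) {
    if (dx^2 + dy^2 + dz^2 > r^2 + 1e-9) next
    p <- idx
    p[, 1] <- p[, 1] + dx; p[, 2] <- p[, 2] + dy; p[, 3] <- p[, 3] + dz
    keep <- p[, 1] >= 1 & p[, 1] <= sh[1] & p[, 2] >= 1 & p[, 2] <= sh[2] &
      p[, 3] >= 1 & p[, 3] <= sh[3]
    out[p[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# real-space point-dipole frequency of a tensor source distribution:
# f(r)/f0 = (1/4pi) (3 (rhat.h)(rhat.m) - h.m) / |r|^3,  m = V X h
# summed over source voxels (O(N_src * N_field) oracle)
brute_tensor_dipole_field <- function(X_list, src_idx, grid, h, f0,
                                      field_idx) {
  co <- qsmsim:::.centered_coords(grid)
  vv <- prod(grid$voxel_size)
  out <- numeric(length(field_idx))
  for (s in src_idx) {
    Xs <- matrix(c(X_list$xx[s], X_list$xy[s], X_list$xz[s],
                   X_list$xy[s], X_list$yy[s], X_list$yz[s],
                   X_list$xz[s], X_list$yz[s], X_list$zz[s]), 3, 3)
    m <- vv * as.vector(Xs %*% h)
    rx <- co$x[field_idx] - co$x[s]
    ry <- co$y[field_idx] - co$y[s]
    rz <- co$z[field_idx] - co$z[s]
    rn <- sqrt(rx^2 + ry^2 + rz^2)
    rh <- (rx * h[1] + ry * h[2] + rz * h[3]) / rn
    rm <- (rx * m[1] + ry * m[2] + rz * m[3]) / rn
    out <- out + f0 / (4 * pi) * (3 * rh * rm - (h[1] * m[1] + h[2] * m[2] +
                                                   h[3] * m[3])) / rn^3
  }
  out
}

# small centred sphere mask on a grid
sphere_mask_at <- function(grid, radius_mm, centre = c(0, 0, 0)) {
  co <- qsmsim:::.centered_coords(grid)
  (co$x - centre[1])^2 + (co$y - centre[2])^2 + (co$z - centre[3])^2 <=
    radius_mm^2
}

# per-voxel eigen oracle using base eigen() in a loop
eigen_oracle <- function(X, idx) {
  cm <- X$components
  t(vapply(idx, function(i) {
    A <- matrix(c(cm$xx[i], cm$xy[i], cm$xz[i],
                  cm$xy[i], cm$yy[i], cm$yz[i],
                  cm$xz[i], cm$yz[i], cm$zz[i]), 3, 3)
    eigen(A, symmetric = TRUE, only.values = TRUE)$values
  }, numeric(3)))
}

relative_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
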