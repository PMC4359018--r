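#' External-field shell mask around a sample
#'
#' The fitting region used in external-field susceptometry: the sample
#' mask dilated by `dilate_out` voxels minus the sample mask dilated by
#' `dilate_in` voxels. Keeping one dilated voxel layer out of the shell
#' avoids partial-volume voxels at the sample surface and any local
#' (exchange / microstructure) offsets inside the sample.
#'
#' @param sample_mask 3D logical array (non-empty, strictly interior).
#' @param dilate_out outer dilation radius in voxels (default 8).
#' @param dilate_in inner exclusion dilation radius in voxels (default 1).
#' @return 3D logical array, disjoint from `dilate(sample_mask, dilate_in)`.
#' @export
shell_mask <- function(sample_mask, dilate_out = 8, dilate_in = 1) {
  if (!any(sample_mask != 0)) stop("sample mask is empty")
  dilate_mask(sample_mask, dilate_out) & !dilate_mask(sample_mask, dilate_in)
}

#' Exclude high-R2* voxels from a fitting mask
#'
#' Keeps only shell voxels whose R2* is below `r2star_max`; used to drop
#' voxels whose frequency is corrupted by nearby air bubbles or other
#' signal voids.
#'
#' @param shell 3D logical fitting mask.
#' @param r2star a [scalar_volume()] in s^-1 on the same grid.
#' @param r2star_max exclusion threshold in s^-1 (default 15).
#' @return 3D logical array.
#' @export
fit_qualify <- function(shell, r2star, r2star_max = 15) {
  if (!inherits(r2star, "scalar_volume") || r2star$units != "s^-1")
    stop("'r2star' must be a scalar_volume in s^-1")
  if (!all(dim(shell) == r2star$grid$shape))
    stop("shell and r2star are on different grids")
  shell & (r2star$values < r2star_max)
}

#' Least-squares bulk susceptibility fit from the external field
#'
#' Fits `f_meas = chi_I F_I + chi_A F_A` jointly over all orientations and
#' all voxels of the fitting mask, where `F_I` and `F_A` are the simulated
#' fields per unit isotropic and anisotropic susceptibility. Solved by QR
#' (orthogonal) decomposition; standard errors follow the classical
#' linear-model covariance `sigma^2 (G^T G)^-1` with
#' `sigma^2 = RSS / (n - p)`.
#'
#' @param meas list of measured [scalar_volume()]s in Hz, one per
#'   orientation (SHARP-filtered like the unit maps).
#' @param unit_iso list of simulated fields per unit chi_I (Hz/ppm).
#' @param unit_aniso list of simulated fields per unit chi_A (Hz/ppm);
#'   ignored when `include_aniso = FALSE`.
#' @param mask 3D logical fitting mask (external shell).
#' @param include_aniso fit the anisotropic column too (default `TRUE`);
#'   `FALSE` gives the isotropic-only variant.
#' @param demean subtract each orientation's mean over the fitting mask
#'   from its measured and unit maps before fitting (default `TRUE`).
#'   A measured frequency map is only defined up to an arbitrary
#'   per-acquisition reference (and background filtering re-references it
#'   to a different region than the fitting shell), so the fit should not
#'   depend on it; demeaning makes it exactly invariant.
#' @return An object of class `bulk_fit`: `chiI`, `chiA`, `se_chiI`,
#'   `se_chiA`, `param_correlation`, `rss` (Hz^2), `n_voxels`, `df`,
#'   `include_aniso`.
#' @export
fit_bulk_chi <- function(meas, unit_iso, unit_aniso = NULL, mask,
                         include_aniso = TRUE, demean = TRUE) {
  vals <- function(x) if (inherits(x, "scalar_volume")) x$values else x
  n_or <- length(meas)
  if (length(unit_iso) != n_or) stop("one unit_iso volume per orientation required")
  if (include_aniso && (is.null(unit_aniso) || length(unit_aniso) != n_or))
    stop("one unit_aniso volume per orientation required")
  idx <- which(mask != 0)
  if (length(idx) < 3L) stop("fitting mask has too few voxels")
  take <- function(v) {
    x <- vals(v)[idx]
    if (demean) x - mean(x) else x
  }
  y <- unlist(lapply(meas, take), use.names = FALSE)
  gI <- unlist(lapply(unit_iso, take), use.names = FALSE)
  G <- if (include_aniso) {
    gA <- unlist(lapply(unit_aniso, take), use.names = FALSE)
    cbind(F_I = gI, F_A = gA)
  } else cbind(F_I = gI)
  p <- ncol(G)
  qrG <- qr(G)
  if (qrG$rank < p)
    stop("rank-deficient design: orientations do not separate chi_I and chi_A")
  beta <- qr.coef(qrG, y)
  res <- y - G %*% beta
  rss <- sum(res^2)
  n <- length(y)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrG))
  covb <- sigma2 * XtXinv
  se <- sqrt(diag(covb))
  structure(list(
    chiI = unname(beta[1]),
    chiA = if (include_aniso) unname(beta[2]) else NA_real_,
    se_chiI = unname(se[1]),
    se_chiA = if (include_aniso) unname(se[2]) else NA_real_,
    param_correlation = if (include_aniso)
      covb[1, 2] / sqrt(covb[1, 1] * covb[2, 2]) else NA_real_,
    rss = rss, n_voxels = length(idx), n_obs = n, df = n - p,
    include_aniso = include_aniso),
    class = "bulk_fit")
}

#' @export
print.bulk_fit <- function(x, ...) {
  cat(sprintf("<bulk_fit> chi_I = %.5f +/- %.5f ppm", x$chiI, x$se_chiI))
  if (x$include_aniso)
    cat(sprintf(", chi_A = %.5f +/- %.5f ppm (R = %.3f)",
                x$chiA, x$se_chiA, x$param_correlation))
  cat(sprintf("\n  RSS = %.4g Hz^2 over %d voxels x %d orientations\n",
              x$rss, x$n_voxels, x$n_obs / x$n_voxels))
  invisible(x)
}

#' Residual frequency map
#'
#' Voxelwise measured minus simulated frequency; the part of the measured
#' field not explained by the bulk susceptibility model.
#'
#' @param meas,sim_fitted [scalar_volume()]s in Hz on the same grid.
#' @return A [scalar_volume()] in Hz.
#' @export
residual_map <- function(meas, sim_fitted) {
  if (meas$units != "Hz" || sim_fitted$units != "Hz") stop("inputs must be in Hz")
  if (!all(meas$grid$shape == sim_fitted$grid$shape))
    stop("inputs are on different grids")
  scalar_volume(meas$values - sim_fitted$values, meas$grid, "Hz",
                mask = meas$mask)
}

#' Mean residual frequency inside the eroded sample
#'
#' Averages a residual map over the sample mask eroded by `erode` voxels
#' (dropping surface voxels subject to partial-volume effects), returning
#' the mean and the population standard deviation over the ROI.
#'
#' @param fR a [scalar_volume()] in Hz.
#' @param sample_mask 3D logical array.
#' @param erode erosion radius in voxels (default 1).
#' @return list with `mean` (Hz), `sd` (Hz), `n` (voxel count).
#' @export
roi_mean_residual <- function(fR, sample_mask, erode = 1) {
  me <- erode_mask(sample_mask, erode)
  if (!any(me)) stop("erosion empties the sample mask")
  v <- fR$values[me]
  list(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)), n = sum(me))
}

#' Fit the sin-squared orientation model to residual frequencies
#'
#' Least-squares fit of `f_R(theta) = A sin^2(theta) + b` to per-angle mean
#' residual frequencies. Angles are reduced by the axial symmetry of the
#' model (theta and 180 - theta are equivalent) before fitting. `A`
#' captures the microstructure-driven orientation dependence; `b` is the
#' orientation-independent offset (microstructure plus exchange).
#'
#' @param thetas_deg angles between the fiber axis and B0, degrees.
#' @param means mean residual frequencies at those angles, Hz.
#' @param weights optional least-squares weights (default unweighted).
#' @return An object of class `orientation_fit`: `A`, `b`, `se_A`, `se_b`
#'   (Hz; `NA` when the design is exactly determined), `rss` (Hz^2),
#'   `fitted`, `df`.
#' @export
fit_orientation_model <- function(thetas_deg, means, weights = NULL) {
  if (length(thetas_deg) != length(means)) stop("angle/value length mismatch")
  th <- thetas_deg %% 180
  th <- pmin(th, 180 - th)
  x <- sin(th * pi / 180)^2
  if (length(unique(round(x, 12))) < 2L)
    stop("all angles are equivalent: the model is rank deficient")
  dat <- data.frame(x = x, y = means)
  fit <- if (is.null(weights)) stats::lm(y ~ x, data = dat)
  else stats::lm(y ~ x, data = dat, weights = weights)
  cf <- stats::coef(fit)
  n <- length(means)
  # vcov warns on exactly interpolating (noise-free) data; SEs are then 0
  se <- if (n > 2L) suppressWarnings(sqrt(diag(stats::vcov(fit))))
  else c(NA_real_, NA_real_)
  structure(list(A = unname(cf[2]), b = unname(cf[1]),
                 se_A = unname(se[2]), se_b = unname(se[1]),
                 rss = sum(stats::residuals(fit)^2),
                 fitted = unname(stats::fitted(fit)),
                 df = n - 2L),
            class = "orientation_fit")
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat(sprintf("<orientation_fit> f_R(theta) = A sin^2(theta) + b\n"))
  cat(sprintf("  A = %.3f +/- %.3f Hz, b = %.3f +/- %.3f Hz, RSS = %.4g Hz^2\n",
              x$A, x$se_A, x$b, x$se_b, x$rss))
  invisible(x)
}

#' Nested-model F test
#'
#' Compares a reduced model (p_reduced parameters, residual sum of squares
#' `rss_reduced`) against a full model that nests it, with
#' `F = ((rss_r - rss_f)/(p_f - p_r)) / (rss_f/(n - p_f))` and the p-value
#' from the upper tail of the F distribution. Used to test whether adding
#' the anisotropic susceptibility column significantly improves the
#' external-field fit.
#'
#' @param rss_reduced,rss_full residual sums of squares (reduced >= full >= 0).
#' @param p_reduced,p_full parameter counts (full > reduced).
#' @param n number of observations (> p_full).
#' @return list with `F` and `p_value`.
#' @export
nested_f_test <- function(rss_reduced, p_reduced, rss_full, p_full, n) {
  if (p_full <= p_reduced) stop("full model must have more parameters")
  if (n <= p_full) stop("need n > p_full observations")
  if (rss_full < 0 || rss_reduced < rss_full)
    stop("require rss_reduced >= rss_full >= 0")
  df1 <- p_full - p_reduced
  df2 <- n - p_full
  Fs <- ((rss_reduced - rss_full) / df1) / (rss_full / df2)
  list(F = Fs, p_value = stats::pf(Fs, df1, df2, lower.tail = FALSE))
}
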