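# Quantitative quality-control indicators: deformation, dissimilarity,
# inhomogeneity, explained-variance baselines and normality testing.

#' Overall affine scaling of a spatial normalization
#'
#' The absolute determinant of the 3x3 linear block of the 4x4 affine
#' transformation matrix: the global volume scaling applied to the image.
#'
#' @param affine 4x4 (or 3x3) numeric matrix.
#' @return Scalar scaling factor.
#' @export
affine_scaling <- function(affine) {
  stopifnot(is.matrix(affine), nrow(affine) %in% c(3L, 4L))
  L <- affine[1:3, 1:3]
  d <- det(L)
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine matrix is singular")
  abs(d)
}

# Central finite differences of one displacement component along one axis,
# one-sided at the volume borders; spacing h in mm.
grad_axis <- function(vol, axis, h) {
  d <- dim(vol)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  denom <- (idx_p - idx_m) * h
  if (axis == 1L) {
    g <- (vol[idx_p, , , drop = FALSE] - vol[idx_m, , , drop = FALSE]) / denom
  } else if (axis == 2L) {
    g <- (vol[, idx_p, , drop = FALSE] - vol[, idx_m, , drop = FALSE]) /
      rep(denom, each = d[1])
  } else {
    g <- (vol[, , idx_p, drop = FALSE] - vol[, , idx_m, drop = FALSE]) /
      rep(denom, each = d[1] * d[2])
  }
  array(g, d)
}

#' Voxelwise Jacobian determinants of a deformation field
#'
#' For a displacement field `u` (mm) the local mapping Jacobian is
#' `I + du/dx`, differentiated by central finite differences (one-sided at
#' volume borders).
#'
#' @param displacement 4D array `nx x ny x nz x 3` of mm displacements.
#' @param voxel_size Grid spacing in mm (length 3).
#' @return 3D array of Jacobian determinants (signed).
#' @export
jacobian_determinant <- function(displacement, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(displacement)) == 4L, dim(displacement)[4] == 3L)
  J <- vector("list", 9)
  k <- 0
  for (comp in 1:3) for (axis in 1:3) {
    k <- k + 1
    J[[k]] <- grad_axis(displacement[, , , comp], axis, voxel_size[axis]) +
      as.numeric(comp == axis)
  }
  # rows = component, cols = axis: det of 3x3 per voxel
  J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
}

#' Non-linear volume change of a deformation, affine contribution removed
#'
#' Sums the absolute voxelwise Jacobian determinants of the total mapping
#' over in-mask (brain) voxels, divided by the affine determinant so that
#' only non-linear volume change remains. With the `"excess"` variant the
#' summand is `|J/|A|| - 1|` instead of `|J|/|A|`.
#'
#' @param field Either a 4D displacement array (`nx x ny x nz x 3`, mm) or a
#'   precomputed 3D Jacobian-determinant volume.
#' @param mask Logical 3D brain mask.
#' @param affine 4x4 affine matrix of the mapping (identity by default).
#' @param voxel_size Grid spacing in mm.
#' @param variant `"sum"` (literal absolute determinants) or `"excess"`
#'   (deviation from volume preservation).
#' @return List with `sum`, `mean` and the number of in-mask voxels.
#' @export
nonlinear_volume_change <- function(field, mask, affine = diag(4),
                                    voxel_size = c(1, 1, 1),
                                    variant = c("sum", "excess")) {
  variant <- match.arg(variant)
  if (!any(mask)) stop("empty brain mask")
  detJ <- if (length(dim(field)) == 4L) {
    jacobian_determinant(field, voxel_size)
  } else {
    field
  }
  stopifnot(identical(dim(detJ), dim(mask)))
  rel <- abs(detJ) / affine_scaling(affine)
  vals <- if (variant == "sum") rel[mask] else abs(rel[mask] - 1)
  list(sum = sum(vals), mean = mean(vals), n_voxels = sum(mask))
}

#' Per-subject dissimilarity from the cohort mean image
#'
#' The cohort mean image is subtracted from each individual image; the sum
#' of absolute voxelwise differences is the divergence-from-the-mean
#' indicator.
#'
#' @param stack A [tissue_stack()] with at least 2 subjects.
#' @param mask Optional logical 3D mask restricting the sum (whole volume by
#'   default).
#' @return Numeric vector, one value per subject.
#' @export
dissimilarity_from_mean <- function(stack, mask = NULL) {
  n <- stack_n_subjects(stack)
  if (n < 2L) stop("dissimilarity needs at least 2 subjects")
  Y <- matrix(stack$data, n, prod(stack_grid_dim(stack)))
  if (!is.null(mask)) Y <- Y[, as.vector(mask), drop = FALSE]
  mu <- colMeans(Y)
  rowSums(abs(sweep(Y, 2, mu)))
}

#' Mean 26-neighborhood inhomogeneity of a probability volume
#'
#' Every voxel whose probability exceeds the threshold is compared to its 26
#' surrounding voxels; the mean absolute deviation per voxel (neighbors
#' outside the volume excluded), averaged over all qualifying voxels, is
#' reported in percent intensity. A fully homogeneous volume scores 0.
#'
#' @param volume 3D probability volume.
#' @param mask_threshold Center-voxel probability threshold (strict).
#' @return Scalar mean absolute deviation in percent.
#' @export
neighborhood_inhomogeneity <- function(volume, mask_threshold = 0.10) {
  d <- dim(volume)
  stopifnot(length(d) == 3L)
  qual <- volume > mask_threshold
  if (!any(qual)) stop("no voxels exceed the threshold")
  sum_abs <- array(0, d)
  count <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- seq_len(d[1]) + dx; sy <- seq_len(d[2]) + dy; sz <- seq_len(d[3]) + dz
    vx <- sx >= 1 & sx <= d[1]; vy <- sy >= 1 & sy <= d[2]; vz <- sz >= 1 & sz <= d[3]
    nb <- volume[sx[vx], sy[vy], sz[vz], drop = FALSE]
    ctr <- volume[vx, vy, vz, drop = FALSE]
    sum_abs[vx, vy, vz] <- sum_abs[vx, vy, vz] + abs(ctr - nb)
    count[vx, vy, vz] <- count[vx, vy, vz] + 1
  }
  mad_per_voxel <- sum_abs / count
  100 * mean(mad_per_voxel[qual])
}

#' Relate per-option metric values to a reference option
#'
#' Divides every value by the reference option's value, so the reference
#' entry is exactly 1.
#'
#' @param values Numeric vector of per-option values.
#' @param reference Index of the reference option (default: the first).
#' @return Numeric vector of ratios.
#' @export
relative_metric <- function(values, reference = 1L) {
  if (values[reference] == 0) stop("reference value is zero")
  values / values[reference]
}

#' Voxelwise polynomial GLM baseline
#'
#' Ordinary least squares per voxel with intercept, age, age squared, age
#' cubed, sex, field strength and quality — the conventional approach the
#' adaptive splines are compared against. Age terms are centered and scaled
#' internally for conditioning; r-squared is unaffected.
#'
#' @param stack A [tissue_stack()].
#' @param X Design matrix with columns `age_months`, `sex`,
#'   `field_strength`, `quality`.
#' @param mask Logical 3D mask (computed at 10% by default).
#' @return List with `r2` (3D volume, NA out of mask) and `mean_r2`.
#' @export
glm_baseline <- function(stack, X, mask = NULL) {
  X <- as.matrix(X)
  if (is.null(mask)) mask <- compute_mask(stack)
  n <- stack_n_subjects(stack)
  a <- scale(X[, "age_months"])
  D <- cbind(1, a, a^2, a^3, X[, "sex"], X[, "field_strength"], X[, "quality"])
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    warning("rank-deficient GLM design; minimum-norm fit used")
  Y <- matrix(stack$data, n, prod(stack_grid_dim(stack)))[, as.vector(mask), drop = FALSE]
  coef <- if (qrD$rank < ncol(D)) ls_minnorm(D, Y) else qr.coef(qrD, Y)
  res <- Y - D %*% coef
  sse <- colSums(res^2)
  mu <- colMeans(Y)
  sst <- colSums(Y^2) - n * mu^2
  r2 <- ifelse(sst > 1e-12, 1 - sse / sst, 0)
  vol <- array(NA_real_, stack_grid_dim(stack))
  vol[as.vector(mask)] <- r2
  list(r2 = vol, mean_r2 = mean(r2))
}

#' Moving-average baseline over age-sorted subjects
#'
#' Centered moving average over the `window_n` nearest-by-rank subjects
#' (edge windows truncated): the conventional way of generating per-age
#' means that the spline fit is compared against.
#'
#' @param values Per-subject values.
#' @param ages Per-subject ages (months); values are sorted by age.
#' @param window_n Window size in subjects (25, 50 or 100 in the reference
#'   protocol; any positive value is accepted).
#' @return Data frame with `age`, `value` and `smoothed`, sorted by age.
#' @export
moving_average_baseline <- function(values, ages, window_n = 25L) {
  n <- length(values)
  stopifnot(length(ages) == n)
  if (window_n > n) stop("window larger than the number of subjects")
  o <- order(ages)
  v <- values[o]
  lo_half <- (window_n - 1L) %/% 2L
  hi_half <- window_n %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - lo_half):min(n, i + hi_half)])
  }, numeric(1))
  data.frame(age = ages[o], value = v, smoothed = sm)
}

#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with
#' estimated mean and variance, with Lilliefors critical values.
#'
#' @param values Numeric sample, `n >= 5`.
#' @param alpha Significance level for the rejection decision.
#' @return List with `statistic`, `p_value` and `reject`.
#' @export
lilliefors_normality <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("Lilliefors test needs at least 5 values")
  lt <- nortest::lillie.test(values)
  list(statistic = unname(lt$statistic),
       p_value = lt$p.value,
       reject = lt$p.value <= alpha)
}
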