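# Generation of six-class tissue priors from fitted voxelwise model sets.

#' Clip a volume to the unit probability interval
#'
#' Spline extrapolation can leave `[0, 1]`; values are clipped and the count
#' of clipped voxels is recorded in attribute `"n_clipped"`.
#'
#' @param volume Numeric array.
#' @return The clipped array.
#' @export
clamp01 <- function(volume) {
  n_clipped <- sum(volume < 0 | volume > 1)
  out <- pmin(pmax(volume, 0), 1)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Enforce six-class probability consistency
#'
#' Segmentation routines expect the six tissue probabilities to sum to 1 in
#' every voxel. Any remaining inconsistency is absorbed by the last class
#' (background): background is set to `1 - sum(first five)`; where that
#' would be negative, background is set to 0 and the other five classes are
#' rescaled proportionally. Voxels that are zero across all classes get
#' background 1 (count reported in attribute `"n_all_zero"`).
#'
#' @param volumes Named list of six clamped 3D volumes in [tissue_classes]
#'   order.
#' @param tol Permitted deviation of the final per-voxel sum from 1.
#' @return A `prior_set`: named list of six volumes summing to 1 per voxel.
#' @export
enforce_class_consistency <- function(volumes, tol = 1e-6) {
  stopifnot(length(volumes) == 6L)
  if (!is.null(names(volumes))) volumes <- volumes[tissue_classes]
  names(volumes) <- tissue_classes
  s5 <- Reduce(`+`, volumes[1:5])
  bg_old <- volumes$background
  all_zero <- s5 == 0 & bg_old == 0
  bg <- 1 - s5
  neg <- bg < 0
  if (any(neg)) {
    scl <- ifelse(neg, 1 / s5, 1)
    for (k in 1:5) volumes[[k]] <- volumes[[k]] * scl
    bg[neg] <- 0
  }
  bg[all_zero] <- 1
  volumes$background <- bg
  total <- Reduce(`+`, volumes)
  stopifnot(max(abs(total - 1)) <= tol)
  structure(volumes, class = "prior_set",
            n_rescaled = sum(neg), n_all_zero = sum(all_zero))
}

#' @export
print.prior_set <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("prior_set: 6 tissue classes on a %dx%dx%d grid (per-voxel sum = 1)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' 3D median filter with replicate padding
#'
#' Each voxel is replaced by the median of its `(2r+1)^3` neighborhood;
#' volume borders are handled by clamping indices (replicate padding). The
#' output never leaves the min-max range of the input neighborhood.
#'
#' @param volume 3D numeric array.
#' @param radius Neighborhood radius in voxels (default 1, i.e. 3x3x3).
#' @return Filtered array of the same dimensions.
#' @export
median_filter_3d <- function(volume, radius = 1L) {
  d <- dim(volume)
  stopifnot(length(d) == 3L, radius >= 0L)
  if (radius == 0L) return(volume)
  offs <- seq.int(-radius, radius)
  w <- length(offs)^3
  neigh <- matrix(0, length(volume), w)
  col <- 0L
  for (dz in offs) for (dy in offs) for (dx in offs) {
    col <- col + 1L
    ix <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    neigh[, col] <- volume[ix, iy, iz]
  }
  mid <- (w + 1L) %/% 2L
  med <- apply(neigh, 1, function(v) sort.int(v, partial = mid)[mid])
  array(med, d)
}

build_request_matrix <- function(fit, request) {
  request <- as.data.frame(request)
  need <- c("age_months", "sex", "field_strength")
  missing <- setdiff(need, names(request))
  if (length(missing))
    stop(sprintf("request is missing column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(request) == 0L) stop("empty prior request")
  sex <- request$sex
  if (is.character(sex) || is.factor(sex)) sex <- as.numeric(toupper(as.character(sex)) == "M")
  fs <- request$field_strength
  if (any(!fs %in% c(0, 1))) fs <- as.numeric(fs == 3)
  X <- cbind(age_months = as.numeric(request$age_months),
             sex = as.numeric(sex),
             field_strength = fs,
             quality = rep(fit$quality_max, nrow(request)))
  rng <- fit$var_ranges
  offenders <- character(0)
  for (j in c("age_months", "sex", "field_strength")) {
    v <- X[, j]
    if (any(v < rng[1, j] - 1e-9 | v > rng[2, j] + 1e-9))
      offenders <- c(offenders,
                     sprintf("%s outside training range [%.4g, %.4g]",
                             j, rng[1, j], rng[2, j]))
  }
  if (length(offenders))
    stop(paste("prior request out of range:", paste(offenders, collapse = "; ")))
  X
}

#' Predict tissue priors for demographic targets ("matched pairs")
#'
#' Generates one map per request row per class, with the data-quality
#' predictor fixed at the best available (maximum) training value, and
#' averages the rows voxelwise. Requests outside the training range of any
#' predictor are hard errors.
#'
#' @param models Named list of [fit_voxelwise()] results (any subset of
#'   [tissue_classes]), all on one grid.
#' @param request Data frame with columns `age_months`, `sex` (`"M"`/`"F"`
#'   or 1/0) and `field_strength` (1.5/3 or 0/1).
#' @return Named list of 3D volumes (one per class), unclamped.
#' @export
predict_priors <- function(models, request) {
  stopifnot(length(models) >= 1L)
  gd <- models[[1]]$grid_dim
  for (m in models) {
    if (!identical(m$grid_dim, gd)) stop("model sets are not on one grid")
  }
  lapply(models, function(fit) {
    X <- build_request_matrix(fit, request)
    vols <- predict_voxelwise(fit, X)
    Reduce(`+`, vols) / length(vols)
  })
}

#' Build a filtered, consistent six-class prior set
#'
#' The full prior-generation pipeline: matched-pairs prediction, clipping to
#' `[0, 1]`, per-class 3D median filtering, then six-class consistency
#' enforcement.
#'
#' @param models Named list of [fit_voxelwise()] results covering all six
#'   [tissue_classes].
#' @param request See [predict_priors()].
#' @param median_radius Median-filter radius (0 disables filtering).
#' @return A `prior_set` with attributes `"n_clipped"` (per class) and the
#'   request echoed in `"request"`.
#' @export
build_priors <- function(models, request, median_radius = 1L) {
  missing <- setdiff(tissue_classes, names(models))
  if (length(missing))
    stop(sprintf("build_priors needs all six classes; missing: %s",
                 paste(missing, collapse = ", ")))
  raw <- predict_priors(models[tissue_classes], request)
  n_clipped <- integer(6)
  names(n_clipped) <- tissue_classes
  vols <- lapply(tissue_classes, function(cl) {
    v <- clamp01(raw[[cl]])
    n_clipped[[cl]] <<- attr(v, "n_clipped")
    if (median_radius > 0L) v <- median_filter_3d(v, median_radius)
    v
  })
  names(vols) <- tissue_classes
  out <- enforce_class_consistency(vols)
  attr(out, "n_clipped") <- n_clipped
  attr(out, "request") <- as.data.frame(request)
  out
}

#' Signed covariate-effect overlay map
#'
#' Generates priors at two settings of one predictor (all other predictors
#' held at `base_row`), subtracts them (first minus second), and zeroes
#' voxels whose absolute difference does not exceed the visualization
#' threshold (default 5% probability).
#'
#' @param models Named list of model sets covering all six classes.
#' @param base_row One-row data frame with `age_months`, `sex`,
#'   `field_strength`.
#' @param predictor Which predictor to vary.
#' @param values Length-2 vector of settings (defaults: both sexes, or both
#'   field strengths).
#' @param threshold Absolute-difference threshold below which voxels are
#'   zeroed.
#' @param median_radius Passed to [build_priors()].
#' @return Named list of signed 3D difference volumes per class.
#' @export
covariate_difference_map <- function(models, base_row,
                                     predictor = c("field_strength", "sex", "age_months"),
                                     values = NULL, threshold = 0.05,
                                     median_radius = 1L) {
  predictor <- match.arg(predictor)
  if (is.null(values)) {
    values <- switch(predictor,
                     field_strength = c(3, 1.5),
                     sex = c("M", "F"),
                     stop("values must be given when varying age_months"))
  }
  stopifnot(length(values) == 2L)
  rows <- lapply(values, function(v) {
    r <- as.data.frame(base_row)
    r[[predictor]] <- v
    r
  })
  pa <- build_priors(models, rows[[1]], median_radius = median_radius)
  pb <- build_priors(models, rows[[2]], median_radius = median_radius)
  out <- lapply(tissue_classes, function(cl) {
    d <- pa[[cl]] - pb[[cl]]
    d[abs(d) <= threshold] <- 0
    d
  })
  names(out) <- tissue_classes
  out
}

#' Write a prior set as one 4D NIfTI plus JSON sidecar
#'
#' Volumes are stored float32 in fixed class order (GM, WM, CSF, bone, soft,
#' background); the sidecar echoes the request and clipping counts.
#'
#' @param priors A `prior_set` from [build_priors()].
#' @param path Output NIfTI path; the sidecar gets `.json` appended.
#' @param voxel_size Voxel edges in mm.
#' @return `path`, invisibly.
#' @export
write_prior_set <- function(priors, path, voxel_size = c(1, 1, 1)) {
  write_tissue_stack(unclass(priors)[tissue_classes], path, voxel_size = voxel_size)
  meta <- list(engine = "tpmars",
               version = as.character(utils::packageVersion("tpmars")),
               classes = tissue_classes,
               request = attr(priors, "request"),
               n_clipped = as.list(attr(priors, "n_clipped")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
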