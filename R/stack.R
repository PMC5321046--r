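#' Fixed six-class tissue order
#'
#' Gray matter, white matter, cerebrospinal fluid, bone, soft tissue,
#' background — the order expected by segmentation routines and used in all
#' prior files.
#' @export
tissue_classes <- c("GM", "WM", "CSF", "bone", "soft", "background")

#' Construct a tissue-probability stack
#'
#' A 4D array of per-subject tissue-class probability volumes on one shared
#' grid, subject order matching the cohort table.
#'
#' @param data 4D numeric array, `n_subjects x nx x ny x nz`, values in
#'   `[0, 1]`.
#' @param class_label One of [tissue_classes].
#' @param voxel_size Voxel edge lengths in mm (length 3).
#' @param affine Optional 4x4 voxel-to-world matrix (carried through, never
#'   used for resampling).
#' @return A `tissue_stack` object.
#' @export
tissue_stack <- function(data, class_label,
                         voxel_size = c(1, 1, 1), affine = NULL) {
  stopifnot(length(dim(data)) == 4L)
  class_label <- match.arg(class_label, tissue_classes)
  rng <- range(data)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop("tissue probabilities must lie in [0, 1]")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(data = data,
                 class_label = class_label,
                 voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "tissue_stack")
}

#' @export
print.tissue_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("tissue_stack [%s]: %d subjects on a %dx%dx%d grid (%.3g x %.3g x %.3g mm)\n",
              x$class_label, d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

stack_grid_dim <- function(stack) dim(stack$data)[-1]

# Cohort-mean 3D volume (matrix-based; apply() over three margins is slow
# on large grids).
stack_mean <- function(stack) {
  d <- dim(stack$data)
  array(colMeans(matrix(stack$data, d[1], prod(d[-1]))), d[-1])
}

subset_mean <- function(data4d, idx) {
  d <- dim(data4d)
  m <- matrix(data4d, d[1], prod(d[-1]))[idx, , drop = FALSE]
  array(colMeans(m), d[-1])
}

stack_n_subjects <- function(stack) dim(stack$data)[1]

voxel_volume <- function(stack) prod(stack$voxel_size)

check_same_grid <- function(stacks, tol = 1e-4) {
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!identical(stack_grid_dim(s), stack_grid_dim(ref)))
      stop("tissue stacks are not on the same grid (dimension mismatch)")
    if (max(abs(s$affine - ref$affine)) > tol)
      stop("tissue stacks are not on the same grid (affine mismatch)")
  }
  invisible(TRUE)
}

#' In-mask voxels for a tissue class
#'
#' A voxel is fitted only where the cohort-average tissue probability
#' strictly exceeds the threshold (default 10%).
#'
#' @param stack A [tissue_stack()].
#' @param threshold Average-probability threshold (strict inequality).
#' @return Logical 3D array.
#' @export
compute_mask <- function(stack, threshold = 0.10) {
  mean_map <- stack_mean(stack)
  mask <- mean_map > threshold
  if (!any(mask))
    stop(sprintf("empty mask for class %s at threshold %.3g", stack$class_label, threshold))
  mask
}

#' Per-subject global tissue volume
#'
#' The total probability mass per subject times the voxel volume: the global
#' signal series driving the initial (global) model fit.
#'
#' @param stack A [tissue_stack()].
#' @param units `"mm3"` or `"mL"`.
#' @return Numeric vector, one value per subject.
#' @export
compute_globals <- function(stack, units = c("mm3", "mL")) {
  units <- match.arg(units)
  v <- apply(stack$data, 1, sum) * voxel_volume(stack)
  if (units == "mL") v <- v / 1000
  v
}

#' Read a per-class 4D NIfTI stack
#'
#' Expects a 4D volume ordered x, y, z, subject; internally the subject
#' dimension comes first.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param class_label One of [tissue_classes].
#' @return A [tissue_stack()].
#' @export
read_tissue_stack <- function(path, class_label) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  stopifnot(length(dim(arr)) == 4L)
  pd <- RNifti::pixdim(img)
  data <- aperm(arr, c(4, 1, 2, 3))
  tissue_stack(data, class_label,
               voxel_size = abs(pd[1:3]),
               affine = RNifti::xform(img))
}

#' Write a tissue stack (or a set of 3D volumes) as 4D NIfTI
#'
#' @param stack A [tissue_stack()], or a list of 3D arrays on one grid.
#' @param path Output file path (.nii or .nii.gz).
#' @param voxel_size Voxel size when `stack` is a list of arrays.
#' @return `path`, invisibly.
#' @export
write_tissue_stack <- function(stack, path, voxel_size = c(1, 1, 1)) {
  if (inherits(stack, "tissue_stack")) {
    arr <- aperm(stack$data, c(2, 3, 4, 1))
    voxel_size <- stack$voxel_size
  } else {
    arr <- array(0, c(dim(stack[[1]]), length(stack)))
    for (i in seq_along(stack)) arr[, , , i] <- stack[[i]]
  }
  attr(arr, "pixdim") <- c(voxel_size, 1)
  img <- RNifti::asNifti(arr, datatype = "float", internal = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}
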