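# Voxelwise spline fitting under the four homogeneity-enforcement options.

subset_refit <- function(model, kept, X, y) {
  out <- model
  out$basis <- model$basis[kept]
  if (!is.null(model$side_knots)) out$side_knots <- model$side_knots[kept]
  B <- model_matrix_mars(out, X)
  cf <- ls_minnorm(B, y)
  out$intercept <- cf[1]
  out$coef <- if (length(cf) > 1) cf[-1] else numeric(0)
  out$training_sse <- sum((y - B %*% cf)^2)
  sst <- sum((y - mean(y))^2)
  out$training_r2 <- if (sst > 0) 1 - out$training_sse / sst else 0
  out
}

#' Fit the global (whole-class) model
#'
#' Fits the cohort's global tissue-volume series, returning both the
#' unpruned forward-pass model and the pruned model. When the constraints
#' request cubic hinges, the unpruned model is converted once and the pruned
#' model is the backbone subset of that shared cubic basis, so that options
#' 1 and 2 of [fit_voxelwise()] operate on exactly nested bases. A penalty
#' of `"cv"` is resolved by [select_penalty_cv()].
#'
#' @param globals Per-subject global values (see [compute_globals()]).
#' @param X Design matrix from [build_design_matrix()].
#' @param constraints A [fit_constraints()] object.
#' @return A `global_fit` list with elements `unpruned`, `pruned`,
#'   `kept_idx`, `penalty`, `r2` and `constraints`.
#' @export
fit_global_model <- function(globals, X, constraints = fit_constraints()) {
  X <- as.matrix(X)
  y <- as.numeric(globals)
  cc <- constraints
  if (is.character(cc$penalty)) cc$penalty <- as.numeric(select_penalty_cv(X, y, cc))
  fwd <- mars_forward(X, y, cc)
  pruned_lin <- backward_prune(fwd, X, y, cc)
  kept <- attr(pruned_lin, "kept_idx")
  if (cc$cubic) {
    unpruned <- to_cubic(fwd, X, y)
    pruned <- subset_refit(unpruned, kept, X, y)
  } else {
    unpruned <- fwd
    pruned <- pruned_lin
  }
  unpruned$penalty <- cc$penalty
  pruned$penalty <- cc$penalty
  structure(list(unpruned = unpruned,
                 pruned = pruned,
                 kept_idx = kept,
                 penalty = cc$penalty,
                 r2 = pruned$training_r2,
                 constraints = cc),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("global fit: %d -> %d basis functions (penalty %.3g, r2 = %.4f)\n",
              length(x$unpruned$basis), length(x$pruned$basis),
              x$penalty, x$r2))
  invisible(x)
}

# Option-3 inheritance: basis-function cap from the pruned global model and
# the smallest strictly-between observation count over its adjacent knot
# pairs (per variable); configured value kept when the global model has
# fewer than two knots on every variable.
inherit_constraints <- function(global_fit, X, constraints) {
  cc <- constraints
  cc$max_final_funcs <- max(1L, length(global_fit$pruned$basis))
  cc$max_initial_funcs <- max(cc$max_initial_funcs, cc$max_final_funcs)
  p <- ncol(X)
  knots_by_var <- rep(list(numeric(0)), p)
  for (bf in global_fit$pruned$basis) for (tm in bf$terms) {
    if (!tm$linear)
      knots_by_var[[tm$var]] <- sort(unique(c(knots_by_var[[tm$var]], tm$knot)))
  }
  gaps <- integer(0)
  for (j in seq_len(p)) {
    ks <- knots_by_var[[j]]
    if (length(ks) >= 2L) {
      for (i in seq_len(length(ks) - 1L))
        gaps <- c(gaps, sum(X[, j] > ks[i] & X[, j] < ks[i + 1L]))
    }
  }
  if (length(gaps)) cc$min_obs_between_knots <- max(1L, min(gaps))
  cc
}

resolve_penalty <- function(constraints, global_fit) {
  if (!is.character(constraints$penalty)) return(constraints$penalty)
  if (!is.null(global_fit)) return(global_fit$penalty)
  stop("penalty is \"cv\": supply a fitted global model or a numeric penalty")
}

intercept_only_model <- function(mu, template) {
  new_mars_model(intercept = mu, coef = numeric(0), basis = list(),
                 cubic = template$cubic, side_knots = list(),
                 var_ranges = template$var_ranges,
                 var_binary = template$var_binary,
                 var_names = template$var_names,
                 training_sse = 0, training_r2 = 0)
}

ls_solve_fast <- function(B, y) {
  cf <- tryCatch({
    z <- qr.coef(qr(B), y)
    z[is.na(z)] <- 0
    z
  }, error = function(e) ls_minnorm(B, y))
  cf
}

#' Fit spline models per voxel under a homogeneity option
#'
#' The four options trade spatial homogeneity against per-voxel flexibility:
#'
#' * **Option 1** (most conservative): the pruned global model's basis is
#'   frozen; only the coefficients are refit per voxel.
#' * **Option 2**: the unpruned global basis is the candidate set per voxel;
#'   coefficients are refit and backward pruning runs per voxel, with the
#'   global backbone (the functions the pruned global model selected)
#'   protected from deletion.
#' * **Option 3**: full per-voxel forward + backward fit, with the final
#'   basis-function cap and the minimum knot distance inherited from the
#'   fitted global model.
#' * **Option 4** (most liberal): fully independent per-voxel fit with the
#'   configured constraints.
#'
#' Voxels whose response variance falls below `1e-12` get intercept-only
#' models; out-of-mask voxels carry the cohort mean for prior assembly.
#'
#' @param stack A [tissue_stack()].
#' @param X Design matrix ([build_design_matrix()]), rows matching subjects.
#' @param constraints A [fit_constraints()] object.
#' @param option Integer 1-4.
#' @param global_fit A [fit_global_model()] result (required for options
#'   1-3).
#' @param mask Optional logical 3D mask; computed with [compute_mask()] at
#'   `mask_threshold` otherwise.
#' @param mask_threshold Average-probability threshold for the mask.
#' @return A `voxelwise_fit` object.
#' @export
fit_voxelwise <- function(stack, X, constraints = fit_constraints(),
                          option = 2L, global_fit = NULL,
                          mask = NULL, mask_threshold = 0.10) {
  option <- as.integer(option)
  if (!option %in% 1:4) stop("option must be 1, 2, 3 or 4")
  if (option <= 3L && is.null(global_fit))
    stop(sprintf("option %d requires a fitted global model", option))
  X <- as.matrix(X)
  n <- stack_n_subjects(stack)
  stopifnot(nrow(X) == n)
  gdim <- stack_grid_dim(stack)
  if (is.null(mask)) mask <- compute_mask(stack, mask_threshold)
  stopifnot(identical(dim(mask), gdim))
  penalty <- resolve_penalty(constraints, global_fit)

  nvox_all <- prod(gdim)
  Yall <- matrix(stack$data, n, nvox_all)
  mask_idx <- which(as.vector(mask))
  Y <- Yall[, mask_idx, drop = FALSE]
  mean_map <- array(colMeans(Yall), gdim)
  mu <- colMeans(Y)
  sst <- colSums(Y^2) - n * mu^2
  degen <- sst < 1e-12
  nvox <- length(mask_idx)
  r2 <- rep(NA_real_, nvox)

  type <- if (option <= 2L) "shared" else "per_voxel"
  coef <- NULL; basis_model <- NULL; models <- NULL

  if (option == 1L) {
    basis_model <- global_fit$pruned
    B <- model_matrix_mars(basis_model, X)
    coef <- ls_minnorm(B, Y)
    sse <- colSums((Y - B %*% coef)^2)
    r2 <- ifelse(sst > 0, 1 - sse / sst, 0)
    if (any(degen)) {
      coef[, degen] <- 0
      coef[1, degen] <- mu[degen]
      r2[degen] <- 0
    }
  } else if (option == 2L) {
    basis_model <- global_fit$unpruned
    B <- model_matrix_mars(basis_model, X)
    m0 <- ncol(B)
    backbone <- global_fit$kept_idx + 1L
    kc <- c(0L, vapply(basis_model$basis, n_knots_of_basis, integer(1)))
    G <- crossprod(B)
    Bty <- crossprod(B, Y)
    yty <- colSums(Y^2)
    max_final <- max(constraints$max_final_funcs, length(backbone))
    coef <- matrix(0, m0, nvox)
    for (v in seq_len(nvox)) {
      if (degen[v]) { coef[1, v] <- mu[v]; r2[v] <- 0; next }
      st <- prune_gram(G, Bty[, v], yty[v], n, kc, penalty, max_final,
                       protected = backbone)
      cf <- ls_solve_fast(B[, st$S, drop = FALSE], Y[, v])
      coef[st$S, v] <- cf
      r2[v] <- 1 - sum((Y[, v] - B[, st$S, drop = FALSE] %*% cf)^2) / sst[v]
    }
  } else {
    cc <- constraints
    cc$penalty <- penalty
    if (option == 3L) cc <- inherit_constraints(global_fit, X, cc)
    template <- list(cubic = cc$cubic, var_ranges = apply(X, 2, range),
                     var_binary = apply(X, 2, function(v) length(unique(v)) == 2L),
                     var_names = colnames(X))
    models <- vector("list", nvox)
    for (v in seq_len(nvox)) {
      if (degen[v]) {
        models[[v]] <- intercept_only_model(mu[v], template)
        r2[v] <- 0
        next
      }
      fit <- mars_fit(X, Y[, v], cc)
      models[[v]] <- fit
      r2[v] <- fit$training_r2
    }
  }

  r2_map <- array(NA_real_, gdim)
  r2_map[mask_idx] <- r2

  structure(list(option = option,
                 class_label = stack$class_label,
                 type = type,
                 basis_model = basis_model,
                 coef = coef,
                 models = models,
                 mask = mask,
                 mask_idx = mask_idx,
                 grid_dim = gdim,
                 voxel_size = stack$voxel_size,
                 affine = stack$affine,
                 mean_map = mean_map,
                 r2 = r2_map,
                 var_names = colnames(X),
                 var_ranges = apply(X, 2, range),
                 quality_max = if ("quality" %in% colnames(X)) max(X[, "quality"]) else NA_real_,
                 penalty = penalty,
                 constraints = constraints,
                 n_subjects = n),
            class = "voxelwise_fit")
}

#' @export
print.voxelwise_fit <- function(x, ...) {
  cat(sprintf("voxelwise_fit [%s], option %d: %d in-mask voxels on %s grid, mean r2 = %.4f\n",
              x$class_label, x$option, length(x$mask_idx),
              paste(x$grid_dim, collapse = "x"),
              mean(x$r2[x$mask_idx])))
  invisible(x)
}

#' Predict per-voxel tissue probabilities for new demographic rows
#'
#' @param fit A `voxelwise_fit`.
#' @param newX Matrix (rows = demographic targets) with the fit's design
#'   columns.
#' @return A list of 3D volumes, one per row of `newX`; out-of-mask voxels
#'   carry the cohort mean map.
#' @export
predict_voxelwise <- function(fit, newX) {
  newX <- as.matrix(newX)
  if (!is.null(fit$var_names) && !is.null(colnames(newX)))
    newX <- newX[, fit$var_names, drop = FALSE]
  if (ncol(newX) != ncol(fit$var_ranges))
    stop("newX column mismatch with fitted design")
  k <- nrow(newX)
  nvox <- length(fit$mask_idx)
  if (fit$type == "shared") {
    B <- model_matrix_mars(fit$basis_model, newX)
    pred <- B %*% fit$coef  # k x nvox
  } else {
    pred <- matrix(0, k, nvox)
    for (v in seq_len(nvox))
      pred[, v] <- predict(fit$models[[v]], newX)
  }
  lapply(seq_len(k), function(i) {
    vol <- fit$mean_map
    vol[fit$mask_idx] <- pred[i, ]
    vol
  })
}

#' Save a voxelwise model set
#'
#' Writes the model container (exact binary round-trip) plus a JSON metadata
#' sidecar (option, constraints, penalty, engine version, mask size).
#'
#' @param fit A `voxelwise_fit`.
#' @param path Output path for the container; the sidecar gets `.json`
#'   appended.
#' @return `path`, invisibly.
#' @export
save_model_set <- function(fit, path) {
  saveRDS(fit, path)
  meta <- list(engine = "tpmars",
               version = as.character(utils::packageVersion("tpmars")),
               class_label = fit$class_label,
               option = fit$option,
               penalty = fit$penalty,
               n_subjects = fit$n_subjects,
               n_mask_voxels = length(fit$mask_idx),
               grid_dim = fit$grid_dim,
               constraints = unclass(fit$constraints))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a voxelwise model set saved with [save_model_set()]
#' @param path Container path.
#' @return A `voxelwise_fit`.
#' @export
load_model_set <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "voxelwise_fit"))
  fit
}
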