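#' Fitting constraints for the spline engine
#'
#' Bundles the sample-count and model-size constraints that govern forward
#' knot placement and backward pruning. The defaults encode the settings used
#' for large lifespan cohorts: 8 final basis functions, 5 times as many
#' (40) initial forward-pass functions, at least 20 observations between
#' knots on the same variable, at least 10 observations between a knot and
#' either end of the data, a curvature penalty chosen by 5-fold
#' cross-validation, and cubic (C1) basis smoothing.
#'
#' @param max_final_funcs Maximum number of basis functions in the pruned
#'   model (intercept excluded).
#' @param max_initial_funcs Maximum number of basis functions the forward
#'   pass may accumulate; defaults to `5 * max_final_funcs`.
#' @param min_obs_between_knots Minimum number of observations (counted with
#'   multiplicity on the knot's own variable) strictly between any two knots.
#' @param min_obs_to_edge Minimum number of observations between a knot and
#'   the smallest/largest observed value of its variable.
#' @param penalty Non-negative curvature penalty entering the GCV effective
#'   parameter count, or the string `"cv"` to select it by k-fold
#'   cross-validation from `penalty_grid`.
#' @param penalty_grid Candidate penalties searched when `penalty = "cv"`.
#' @param cv_folds Number of cross-validation folds.
#' @param max_interaction Maximum order (number of hinge factors) of a basis
#'   function; 2 allows pairwise products.
#' @param cubic Convert the pruned model to C1 piecewise-cubic hinges and
#'   refit its coefficients.
#' @param knot_thinning Maximum number of candidate knot values considered
#'   per variable at each forward step. Candidates are always observed data
#'   values; when more are admissible than this cap, an evenly index-spaced
#'   subset (keeping the first and last) is searched.
#' @param rng_seed Integer seed used for any internal randomness
#'   (cross-validation fold assignment).
#'
#' @return An object of class `fit_constraints`.
#' @export
fit_constraints <- function(max_final_funcs = 8L,
                            max_initial_funcs = 5L * max_final_funcs,
                            min_obs_between_knots = 20L,
                            min_obs_to_edge = 10L,
                            penalty = "cv",
                            penalty_grid = 0:5,
                            cv_folds = 5L,
                            max_interaction = 2L,
                            cubic = TRUE,
                            knot_thinning = 64L,
                            rng_seed = 1L) {
  max_final_funcs <- as.integer(max_final_funcs)
  max_initial_funcs <- as.integer(max_initial_funcs)
  stopifnot(max_final_funcs >= 1L,
            max_initial_funcs >= max_final_funcs,
            min_obs_between_knots >= 1L,
            min_obs_to_edge >= 1L,
            cv_folds >= 2L,
            max_interaction >= 1L,
            knot_thinning >= 2L)
  if (is.character(penalty)) {
    if (!identical(penalty, "cv")) stop("penalty must be a non-negative number or \"cv\"")
  } else if (!is.numeric(penalty) || penalty < 0) {
    stop("penalty must be a non-negative number or \"cv\"")
  }
  structure(list(max_final_funcs = max_final_funcs,
                 max_initial_funcs = max_initial_funcs,
                 min_obs_between_knots = as.integer(min_obs_between_knots),
                 min_obs_to_edge = as.integer(min_obs_to_edge),
                 penalty = penalty,
                 penalty_grid = as.numeric(penalty_grid),
                 cv_folds = as.integer(cv_folds),
                 max_interaction = as.integer(max_interaction),
                 cubic = isTRUE(cubic),
                 knot_thinning = as.integer(knot_thinning),
                 rng_seed = as.integer(rng_seed)),
            class = "fit_constraints")
}

#' @export
print.fit_constraints <- function(x, ...) {
  cat("MARS fit constraints:\n")
  cat(sprintf("  basis functions: %d final / %d initial (interaction order <= %d)\n",
              x$max_final_funcs, x$max_initial_funcs, x$max_interaction))
  cat(sprintf("  knot spacing: >= %d obs between knots, >= %d obs to data edge\n",
              x$min_obs_between_knots, x$min_obs_to_edge))
  pen <- if (identical(x$penalty, "cv")) {
    sprintf("%d-fold CV over {%s}", x$cv_folds, paste(x$penalty_grid, collapse = ", "))
  } else {
    format(x$penalty)
  }
  cat(sprintf("  penalty: %s; cubic: %s; seed: %d\n", pen, x$cubic, x$rng_seed))
  invisible(x)
}

# Evaluate a block of code with a temporary RNG state seeded by `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
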