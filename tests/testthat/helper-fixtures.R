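# Shared fixtures built in code.

toy_cohort_df <- function(n = 4) {
  data.frame(subject_id = sprintf("s%02d", seq_len(n)),
             age_months = seq(24, by = 30, length.out = n),
             sex = rep(c("M", "F"), length.out = n),
             field_strength = rep(c(1.5, 3), length.out = n),
             resolution = seq(1.0, by = 0.05, length.out = n),
             cnr = rep(1, n), inr = rep(1, n),
             stringsAsFactors = FALSE)
}

write_toy_cohort <- function(df = toy_cohort_df(), path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# Small, fast constraint set for unit tests.
quick_constraints <- function(cubic = FALSE, penalty = 1, ...) {
  fit_constraints(max_final_funcs = 5, max_initial_funcs = 15,
                  min_obs_between_knots = 10, min_obs_to_edge = 6,
                  penalty = penalty, cubic = cubic, ...)
}

# A small fitted phantom (all six classes, option by argument), memoised per
# test file run.
fit_phantom_models <- function(spec, constraints, option = 2L,
                               classes = tissue_classes) {
  ph <- generate_cohort(spec)
  X <- ph$design
  models <- list()
  for (cl in classes) {
    st <- ph$stacks[[cl]]
    gf <- fit_global_model(compute_globals(st), X, constraints)
    models[[cl]] <- fit_voxelwise(st, X, constraints, option = option,
                                  global_fit = gf)
  }
  list(phantom = ph, X = X, models = models)
}

# Exhaustive-search oracle for the first forward-pass knot: evaluates every
# admissible knot of every variable by direct least squares on
# [1, (x-t)+, (t-x)+] and applies the engine's tie-break order.
oracle_first_knot <- function(X, y, edge) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- sort(X[, j])
    n <- length(xs)
    if (n < 2 * edge + 1) next
    for (t in unique(xs[(edge + 1):(n - edge)])) {
      B <- cbind(1, pmax(X[, j] - t, 0), pmax(t - X[, j], 0))
      sse <- sum(stats::lm.fit(B, y)$residuals^2)
      if (is.null(best) || sse < best$sse - 1e-12 ||
          (abs(sse - best$sse) <= 1e-9 * max(best$sse, 1e-12) &&
           (j < best$var || (j == best$var && t < best$knot)))) {
        best <- list(var = j, knot = t, sse = sse)
      }
    }
  }
  best
}

# Brute-force 26-neighborhood inhomogeneity by explicit enumeration.
oracle_inhomogeneity <- function(vol, threshold = 0.10) {
  d <- dim(vol)
  vals <- c()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (vol[x, y, z] <= threshold) next
    devs <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nx <- x + dx; ny <- y + dy; nz <- z + dz
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
      devs <- c(devs, abs(vol[x, y, z] - vol[nx, ny, nz]))
    }
    vals <- c(vals, mean(devs))
  }
  100 * mean(vals)
}
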