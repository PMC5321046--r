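test_that("hinge evaluates the truncated-linear pieces", {
  expect_equal(hinge(5, 3, 1), 2)
  expect_equal(hinge(2, 3, 1), 0)
  expect_equal(hinge(3, 3, 1), 0)
  expect_equal(hinge(3, 3, -1), 0)
  expect_equal(hinge(2, 3, -1), 1)
})

test_that("prediction is intercept plus coefficient-weighted basis evaluations", {
  m0 <- tpmars:::new_mars_model(0.37, numeric(0), list(),
                                var_ranges = matrix(c(0, 10), 2),
                                var_binary = FALSE)
  expect_equal(predict(m0, cbind(1:5)), rep(0.37, 5))

  b1 <- list(terms = list(tpmars:::new_term(1, 3, 1)))
  m1 <- tpmars:::new_mars_model(1, 2, list(b1),
                                var_ranges = matrix(c(0, 10), 2),
                                var_binary = FALSE)
  expect_equal(predict(m1, cbind(5)), 5)
  expect_error(predict(m1, cbind(1, 2)), "columns")
})

test_that("forward pass fits noiseless linear data exactly and honors knot admissibility", {
  set.seed(1)
  x <- sort(runif(40, 0, 10))
  y <- 2 * x + 1
  cc <- fit_constraints(max_final_funcs = 4, min_obs_between_knots = 5,
                        min_obs_to_edge = 3, penalty = 0, cubic = FALSE)
  fwd <- mars_forward(cbind(x = x), y, cc)
  expect_lt(fwd$training_sse, 1e-9)

  # n = 25 sorted observations, edge 10, between 20: only sorted positions
  # 11..15 are admissible, and at most one knot fits on the variable
  xs <- sort(runif(25))
  ak <- tpmars:::admissible_knots(xs, 10, numeric(0), 20, 64)
  expect_equal(ak, unique(xs[11:15]))
  ak2 <- tpmars:::admissible_knots(xs, 10, xs[13], 20, 64)
  expect_length(ak2, 0)

  # constant response: intercept-only model
  fc <- mars_forward(cbind(x = x), rep(2, 40), cc)
  expect_length(fc$basis, 0)
  expect_equal(fc$intercept, 2)

  expect_error(mars_forward(cbind(x = x[1:5]), y[1:5],
                            fit_constraints(min_obs_to_edge = 10)),
               "at least")
})

test_that("first selected knot matches exhaustive search on tiny instances", {
  cc <- fit_constraints(max_final_funcs = 2, max_initial_funcs = 2,
                        min_obs_between_knots = 1, min_obs_to_edge = 2,
                        penalty = 0, cubic = FALSE)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(8:12, 1)
    x <- sort(runif(n, 0, 1))
    y <- runif(1, -2, 2) + runif(1, -3, 3) * pmax(x - x[sample(3:(n - 2), 1)], 0) +
      rnorm(n, 0, 0.1)
    fwd <- mars_forward(cbind(x), y, cc)
    expect_gte(length(fwd$basis), 1)
    engine_knot <- fwd$basis[[1]]$terms[[1]]$knot
    oracle <- oracle_first_knot(cbind(x), y, edge = 2)
    expect_equal(engine_knot, oracle$knot)
  }
})

test_that("backward pruning removes redundancy and never worsens GCV", {
  set.seed(4)
  n <- 60
  x <- runif(n, 0, 10)
  y <- 1 + 0.5 * pmax(x - 5, 0) + rnorm(n, 0, 0.05)
  cc <- fit_constraints(max_final_funcs = 4, max_initial_funcs = 10,
                        min_obs_between_knots = 5, min_obs_to_edge = 4,
                        penalty = 1, cubic = FALSE)
  fwd <- mars_forward(cbind(x = x), y, cc)
  pr <- backward_prune(fwd, cbind(x = x), y, cc)
  nk <- function(m) sum(vapply(m$basis, tpmars:::n_knots_of_basis, integer(1)))
  gcv_fwd <- gcv_score(fwd$training_sse, n, length(fwd$basis), nk(fwd), 1)
  gcv_pr <- gcv_score(pr$training_sse, n, length(pr$basis), nk(pr), 1)
  expect_lte(gcv_pr, gcv_fwd + 1e-12)
  expect_lte(length(pr$basis), cc$max_final_funcs)

  # a duplicated basis function is pruned at zero SSE cost
  dup <- fwd
  dup$basis <- c(fwd$basis, fwd$basis[1])
  dup$coef <- c(fwd$coef, 0)
  pr2 <- backward_prune(dup, cbind(x = x), y, cc)
  expect_lte(pr2$training_sse, pr$training_sse + 1e-8)

  # intercept-only models pass through unchanged
  m0 <- mars_forward(cbind(x = x), rep(1, n), cc)
  expect_identical(length(backward_prune(m0, cbind(x = x), rep(1, n), cc)$basis), 0L)
})

test_that("gcv follows the penalized closed form", {
  n <- 100
  expect_equal(gcv_score(2, n, 0, 0, 0), (2 / n) / (1 - 1 / n)^2)
  expect_equal(gcv_score(4, n, 3, 2, 1.5), 2 * gcv_score(2, n, 3, 2, 1.5))
  g <- vapply(c(0, 1, 2, 3), function(p) gcv_score(2, n, 4, 4, p), numeric(1))
  expect_true(all(diff(g) > 0))
  expect_equal(gcv_score(1, 10, 20, 5, 1), Inf)
})

test_that("cross-validated penalty selection is deterministic with lawful tie-breaks", {
  set.seed(9)
  n <- 60
  x <- runif(n, 0, 10)
  X <- cbind(x = x)
  cc <- fit_constraints(max_final_funcs = 3, max_initial_funcs = 6,
                        min_obs_between_knots = 6, min_obs_to_edge = 4,
                        penalty = "cv", penalty_grid = c(0, 2, 4),
                        cubic = FALSE, rng_seed = 11)
  # noiseless linear data: every penalty ties, smallest returned
  y_lin <- 3 * x - 1
  expect_equal(as.numeric(select_penalty_cv(X, y_lin, cc)), 0)
  # identical selection across runs under one seed
  y <- 1 + pmax(x - 4, 0) + rnorm(n, 0, 0.5)
  expect_equal(as.numeric(select_penalty_cv(X, y, cc)),
               as.numeric(select_penalty_cv(X, y, cc)))
  expect_error(select_penalty_cv(X, y, cc, grid = numeric(0)), "empty")
})

test_that("heavy noise on sharp piecewise-linear truth favors a positive penalty", {
  cc <- fit_constraints(max_final_funcs = 3, max_initial_funcs = 10,
                        min_obs_between_knots = 4, min_obs_to_edge = 3,
                        penalty = "cv", penalty_grid = c(0, 2, 4),
                        cubic = FALSE)
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    x <- runif(n, 0, 10)
    y <- pmax(x - 5, 0) + rnorm(n, 0, 1.5)
    cc$rng_seed <- seed
    hits <- hits + (as.numeric(select_penalty_cv(cbind(x = x), y, cc)) > 0)
  }
  expect_gt(hits / 20, 0.5)
})

test_that("r_squared is the explained-variance proportion", {
  set.seed(2)
  x <- runif(80, 0, 10)
  y <- 2 + pmax(x - 3, 0) + rnorm(80, 0, 0.2)
  cc <- quick_constraints()
  fit <- mars_fit(cbind(x = x), y, cc)
  # equals squared Pearson correlation of fitted vs observed
  expect_equal(r_squared(fit, cbind(x = x), y),
               cor(predict(fit, cbind(x = x)), y)^2, tolerance = 1e-10)
  # perfect fit
  expect_equal(r_squared(fit, cbind(x = x), predict(fit, cbind(x = x))), 1)
  # an intercept-only model (predicting the response mean) explains nothing
  m0 <- tpmars:::new_mars_model(mean(y), numeric(0), list(),
                                var_ranges = matrix(range(x), 2),
                                var_binary = FALSE)
  expect_equal(r_squared(m0, cbind(x = x), y), 0)
  expect_warning(r_squared(fit, cbind(x = x), rep(1, 80)), "zero variance")
})

test_that("cubic conversion is C1 and matches linear hinges outside side-knot spans", {
  set.seed(5)
  n <- 120
  x <- runif(n, 0, 10)
  y <- sin(x) + rnorm(n, 0, 0.05)
  cc <- fit_constraints(max_final_funcs = 5, max_initial_funcs = 12,
                        min_obs_between_knots = 8, min_obs_to_edge = 5,
                        penalty = 1, cubic = FALSE)
  lin <- mars_fit(cbind(x = x), y, cc)
  cub <- to_cubic(lin, cbind(x = x), y)
  expect_true(cub$cubic)

  # every hinge with side knots: value and first derivative continuous
  for (m in seq_along(cub$basis)) {
    tm <- cub$basis[[m]]$terms[[1]]
    sd_ <- cub$side_knots[[m]][[1]]
    if (is.null(sd_)) next
    for (kn in sd_) {
      h <- 1e-6
      f <- function(z) tpmars:::cubic_hinge(z, tm$knot, sd_[1], sd_[2], tm$dir)
      expect_lt(abs(f(kn + h) - f(kn - h)), 1e-5)
      dl <- (f(kn) - f(kn - h)) / h
      dr <- (f(kn + h) - f(kn)) / h
      expect_lt(abs(dl - dr), 1e-4)
    }
    # exact agreement with the linear hinge outside the span
    far <- c(sd_[1] - 0.5, sd_[2] + 0.5)
    expect_equal(unname(vapply(far, f, numeric(1))),
                 unname(hinge(far, tm$knot, tm$dir)))
  }

  # the cubic refit still describes the smooth truth well
  expect_gt(cub$training_r2, 0.8)

  # a model with no hinges is unchanged
  m0 <- mars_fit(cbind(x = x), rep(2, n), cc)
  expect_equal(predict(to_cubic(m0, cbind(x = x), rep(2, n)), cbind(x = x)),
               predict(m0, cbind(x = x)))
})

test_that("constrained fits are nested within the unconstrained engine", {
  set.seed(7)
  n <- 60
  x <- runif(n, 0, 10)
  y <- pmax(x - 3, 0) - 0.5 * pmax(x - 6, 0) + rnorm(n, 0, 0.1)
  constrained <- fit_constraints(max_final_funcs = 6, max_initial_funcs = 12,
                                 min_obs_between_knots = 15, min_obs_to_edge = 8,
                                 penalty = 0, cubic = FALSE)
  free <- fit_constraints(max_final_funcs = 12, max_initial_funcs = 12,
                          min_obs_between_knots = 1, min_obs_to_edge = 1,
                          penalty = 0, cubic = FALSE)
  f_con <- mars_forward(cbind(x = x), y, constrained)
  f_free <- mars_forward(cbind(x = x), y, free)
  expect_lte(f_free$training_sse, f_con$training_sse + 1e-10)
})

test_that("binary predictors enter as single linear terms", {
  set.seed(8)
  n <- 80
  X <- cbind(x = runif(n, 0, 10), g = rbinom(n, 1, 0.5))
  y <- 1 + 0.8 * X[, "g"] + rnorm(n, 0, 0.05)
  cc <- quick_constraints()
  fit <- mars_fit(X, y, cc)
  gterms <- unlist(lapply(fit$basis, function(b)
    vapply(b$terms, function(t) t$var == 2, logical(1))))
  expect_true(any(gterms))
  for (b in fit$basis) for (tm in b$terms) {
    if (tm$var == 2) expect_true(tm$linear)
  }
  expect_equal(unname(predict(fit, cbind(x = 5, g = 1)) -
                        predict(fit, cbind(x = 5, g = 0))), 0.8,
               tolerance = 0.05)
})

test_that("JSON serialization reproduces predictions", {
  set.seed(10)
  n <- 100
  X <- cbind(a = runif(n, 0, 10), b = rbinom(n, 1, 0.5))
  y <- 2 + pmax(X[, 1] - 4, 0) + 0.3 * X[, 2] + rnorm(n, 0, 0.1)
  fit <- mars_fit(X, y, quick_constraints(cubic = TRUE))
  path <- tempfile(fileext = ".json")
  write_mars_model(fit, path)
  back <- read_mars_model(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
})
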