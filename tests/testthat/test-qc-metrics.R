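test_that("affine scaling is the absolute determinant of the linear block", {
  expect_equal(affine_scaling(diag(4)), 1)
  expect_equal(affine_scaling(diag(c(1.2, 1.2, 1.2, 1))), 1.728)
  th <- 0.7
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(affine_scaling(rot), 1)
  expect_error(affine_scaling(matrix(0, 4, 4)), "singular")
})

test_that("nonlinear volume change matches closed-form Jacobians", {
  g <- c(24, 8, 8)
  mask <- array(TRUE, g)

  # identity field: every voxel preserves volume
  idf <- generate_deformation(g, kind = "identity")
  out <- nonlinear_volume_change(idf$displacement, mask)
  expect_equal(out$sum, prod(g))
  expect_equal(out$mean, 1)

  # sinusoidal field with analytic determinant, 1 mm grid
  sf <- generate_deformation(g, voxel_size = c(1, 1, 1), kind = "sinusoidal",
                             amplitude = 3, freq = 0.1)
  num <- nonlinear_volume_change(sf$displacement, mask, voxel_size = c(1, 1, 1))
  ana <- mean(abs(sf$jacobian_analytic))
  expect_lt(abs(num$mean - ana) / ana, 0.01)

  # composing with a global affine scale cancels out after affine removal
  s <- 1.3
  x_mm <- (seq_len(g[1]) - 1)
  total <- sf$displacement
  # total mapping y = s * (x + u(x)); displacement y - x
  total[, , , 1] <- array(s * (x_mm + sf$displacement[1:g[1], 1, 1, 1]) - x_mm, g)
  for (ax in 2:3) {
    coord <- slice.index(array(0, g), ax) - 1
    total[, , , ax] <- (s - 1) * coord
  }
  scaled <- nonlinear_volume_change(total, mask, affine = diag(c(s, s, s, 1)),
                                    voxel_size = c(1, 1, 1))
  plain <- nonlinear_volume_change(sf$displacement, mask, voxel_size = c(1, 1, 1))
  expect_equal(scaled$mean, plain$mean, tolerance = 1e-8)

  expect_error(nonlinear_volume_change(idf$displacement, array(FALSE, g)),
               "empty")
})

test_that("dissimilarity from the mean image follows the arithmetic identities", {
  arr <- array(0.4, c(3, 4, 4, 4))
  expect_equal(dissimilarity_from_mean(tissue_stack(arr, "GM")), rep(0, 3))

  two <- array(c(0.2, 0.6), c(2, 1, 1, 1))
  expect_equal(dissimilarity_from_mean(tissue_stack(two, "GM")), c(0.2, 0.2))

  set.seed(50)
  arr2 <- array(runif(5 * 64, 0, 0.5), c(5, 4, 4, 4))
  base <- dissimilarity_from_mean(tissue_stack(arr2, "GM"))
  shifted <- dissimilarity_from_mean(tissue_stack(arr2 + 0.3, "GM"))
  expect_equal(shifted, base)

  expect_error(dissimilarity_from_mean(tissue_stack(two[1, , , , drop = FALSE], "GM")),
               "2 subjects")
})

test_that("neighborhood inhomogeneity matches brute-force enumeration", {
  expect_equal(neighborhood_inhomogeneity(array(0.5, c(4, 4, 4))), 0)

  # the documented 3x3x3 worked case: center 1.0 among 0.2 neighbors
  v <- array(0.2, c(3, 3, 3))
  v[2, 2, 2] <- 1
  expect_equal(neighborhood_inhomogeneity(v), oracle_inhomogeneity(v))

  # random volumes: exact agreement with explicit 26-neighbor enumeration
  for (seed in 1:5) {
    set.seed(seed)
    r <- array(runif(125), c(5, 5, 5))
    expect_equal(neighborhood_inhomogeneity(r), oracle_inhomogeneity(r),
                 tolerance = 1e-12)
  }

  # rescaling by s > 1 rescales the metric (all voxels stay supra-threshold)
  r2 <- array(runif(125, 0.2, 0.45), c(5, 5, 5))
  expect_equal(neighborhood_inhomogeneity(2 * r2),
               2 * neighborhood_inhomogeneity(r2))

  expect_error(neighborhood_inhomogeneity(array(0.01, c(3, 3, 3))), "threshold")
})

test_that("relative metric normalizes to the reference option", {
  expect_equal(relative_metric(c(2, 3, 4, 5)), c(1, 1.5, 2, 2.5))
  expect_equal(relative_metric(c(2, 3, 4, 5))[1], 1.00)
  # relabeling non-reference options permutes outputs
  expect_equal(relative_metric(c(2, 5, 4, 3)), c(1, 2.5, 2, 1.5))
  expect_error(relative_metric(c(0, 1)), "zero")
})

test_that("the polynomial GLM baseline recovers polynomial truth", {
  set.seed(51)
  n <- 100
  X <- cbind(age_months = runif(n, 13, 900), sex = rbinom(n, 1, 0.5),
             field_strength = rbinom(n, 1, 0.7), quality = rnorm(n))
  a <- drop(scale(X[, 1]))
  y <- 0.5 + 0.05 * a + 0.03 * a^2 - 0.02 * a^3 + 0.02 * X[, 2]
  arr <- array(rep(pmin(pmax(y, 0), 1), 27), c(n, 3, 3, 3))
  gl <- glm_baseline(tissue_stack(arr, "GM"), X,
                     mask = array(TRUE, c(3, 3, 3)))
  expect_gt(gl$mean_r2, 0.999)

  cst <- tissue_stack(array(0.4, c(n, 3, 3, 3)), "GM")
  gl0 <- glm_baseline(cst, X, mask = array(TRUE, c(3, 3, 3)))
  expect_equal(gl0$mean_r2, 0)
})

test_that("moving-average baseline smooths by rank windows and blunts peaks", {
  v <- rep(2, 10)
  out <- moving_average_baseline(v, 1:10, 5)
  expect_equal(out$smoothed, v)
  out1 <- moving_average_baseline(rnorm(10), 1:10, 1)
  expect_equal(out1$smoothed, out1$value)

  peak <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0)
  m3 <- max(moving_average_baseline(peak, 1:11, 3)$smoothed)
  m5 <- max(moving_average_baseline(peak, 1:11, 5)$smoothed)
  expect_lt(m5, m3)
  expect_lt(m3, max(peak))

  expect_error(moving_average_baseline(peak, 1:11, 50), "larger")
})

test_that("Lilliefors test calibrates on normal and rejects exponential samples", {
  keep <- 0
  for (seed in 1:50) {
    set.seed(seed)
    keep <- keep + !lilliefors_normality(rnorm(1000))$reject
  }
  expect_gte(keep / 50, 0.9)

  rej <- 0
  for (seed in 1:50) {
    set.seed(seed)
    rej <- rej + lilliefors_normality(rexp(200))$reject
  }
  expect_gte(rej / 50, 0.9)

  # statistic is invariant under affine transformation
  set.seed(99)
  x <- rnorm(200)
  expect_equal(lilliefors_normality(x)$statistic,
               lilliefors_normality(3 * x - 7)$statistic)

  expect_error(lilliefors_normality(rnorm(3)), "at least 5")
})

test_that("gold-standard comparison scores reproduce under a fixed seed", {
  fx <- fit_phantom_models(phantom_spec(grid = c(6, 6, 6), n_subjects = 40,
                                        rng_seed = 60),
                           fit_constraints(max_final_funcs = 3,
                                           max_initial_funcs = 8,
                                           min_obs_between_knots = 6,
                                           min_obs_to_edge = 4,
                                           penalty = 1, cubic = TRUE),
                           classes = "GM")
  stacks <- fx$phantom$stacks["GM"]

  # the full population as "subgroup": the average map is the gold standard
  rep_full <- compare_to_gold_standard(stacks, fx$models, fx$X,
                                       group_sizes = 40, repeats = 1, seed = 1)
  avg_row <- subset(rep_full$values, method == "average")
  expect_equal(avg_row$disagreement, 0)

  ra <- compare_to_gold_standard(stacks, fx$models, fx$X, group_sizes = c(10, 20),
                                 repeats = 3, seed = 17)
  rb <- compare_to_gold_standard(stacks, fx$models, fx$X, group_sizes = c(10, 20),
                                 repeats = 3, seed = 17)
  expect_identical(ra$values, rb$values)
  expect_error(compare_to_gold_standard(stacks, fx$models, fx$X,
                                        group_sizes = 100, repeats = 1, seed = 1),
               "exceeds")

  sa <- shrinking_population_curve(stacks, fx$models, fx$X, subgroup_n = 10,
                                   repeats = 2, step = 10, min_n = 20, seed = 4)
  sb <- shrinking_population_curve(stacks, fx$models, fx$X, subgroup_n = 10,
                                   repeats = 2, step = 10, min_n = 20, seed = 4)
  expect_identical(sa$values, sb$values)
})
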