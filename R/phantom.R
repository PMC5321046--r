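# Seeded phantom cohorts: demographics plus six-class probability volumes
# with known ground truth, for validating the whole pipeline.

#' Specification of a phantom cohort
#'
#' The phantom is a spherical six-layer "head" (WM core, GM shell, CSF rim,
#' bone, soft tissue, background) on a cube of fixed 128-mm physical extent.
#' Class memberships are smooth logistic partitions of unity along the
#' radius, so the six classes sum to 1 before noise. Three covariate effects
#' with distinct spatial signatures are planted: an age trajectory
#' (logistic rise times logistic decline) exchanging mass between GM and WM
#' at their interface, a sex offset exchanging GM and CSF at theirs, and a
#' field-strength offset at the GM/WM interface. Observation noise is
#' Gaussian with a per-subject standard deviation decreasing in the combined
#' quality indicator.
#'
#' @param grid Grid dimensions (length 3).
#' @param n_subjects Cohort size.
#' @param age_range Age range in months.
#' @param traj_amp Peak amplitude of the age trajectory (probability units).
#' @param rise_t50,rise_scale Months: midpoint and scale of the logistic
#'   rise.
#' @param fall_t50,fall_scale Months: midpoint and scale of the logistic
#'   decline.
#' @param sex_amp Male-vs-female probability offset at the GM/CSF interface.
#' @param field_amp 3T-vs-1.5T probability offset at the GM/WM interface.
#' @param sigma0 Baseline noise standard deviation (probability units).
#' @param sigma_quality_slope Exponential decay rate of sigma per z-unit of
#'   quality.
#' @param prob_3t Proportion of 3T scans.
#' @param young_fraction,young_max Ages are drawn from a mixture:
#'   `young_fraction` of subjects uniform on `[age_range[1], young_max]`,
#'   the rest uniform on `[young_max, age_range[2]]` — mirroring the
#'   pediatric enrichment of pooled lifespan cohorts, so childhood
#'   trajectories are adequately sampled.
#' @param boundaries,boundary_width Radial class boundaries and logistic
#'   transition width (normalized radius units).
#' @param rng_seed Mandatory integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(16, 16, 16), n_subjects = 200L,
                         age_range = c(13, 900),
                         traj_amp = 0.12, rise_t50 = 60, rise_scale = 25,
                         fall_t50 = 480, fall_scale = 200,
                         sex_amp = 0.03, field_amp = 0.05,
                         sigma0 = 0.02, sigma_quality_slope = 0.25,
                         prob_3t = 0.7,
                         young_fraction = 0.5, young_max = 250,
                         boundaries = c(0.35, 0.62, 0.72, 0.82, 0.92),
                         boundary_width = 0.06,
                         rng_seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid >= 4L), n_subjects >= 4L,
            age_range[1] > 0, age_range[2] > age_range[1],
            traj_amp >= 0, sex_amp >= 0, field_amp >= 0, sigma0 >= 0,
            length(boundaries) == 5L, all(diff(boundaries) > 0),
            !is.null(rng_seed))
  if (traj_amp + sex_amp + field_amp > 0.5)
    stop("combined effect amplitudes too large: probabilities would leave [0, 1]")
  structure(list(grid = as.integer(grid), n_subjects = as.integer(n_subjects),
                 age_range = age_range, traj_amp = traj_amp,
                 rise_t50 = rise_t50, rise_scale = rise_scale,
                 fall_t50 = fall_t50, fall_scale = fall_scale,
                 sex_amp = sex_amp, field_amp = field_amp,
                 sigma0 = sigma0, sigma_quality_slope = sigma_quality_slope,
                 prob_3t = prob_3t,
                 young_fraction = young_fraction, young_max = young_max,
                 boundaries = boundaries,
                 boundary_width = boundary_width,
                 voxel_size = 128 / as.integer(grid),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Age trajectory of the phantom's GM/WM exchange
#'
#' `amp * plogis((age - rise_t50)/rise_scale) * plogis((fall_t50 - age)/fall_scale)`:
#' a logistic rise in childhood followed by a logistic decline in adulthood.
#'
#' @param age_months Ages in months.
#' @param spec A [phantom_spec()].
#' @return Trajectory values (probability units).
#' @export
phantom_trajectory <- function(age_months, spec) {
  spec$traj_amp *
    stats::plogis((age_months - spec$rise_t50) / spec$rise_scale) *
    stats::plogis((spec$fall_t50 - age_months) / spec$fall_scale)
}

phantom_base_maps <- function(spec) {
  g <- spec$grid
  ax <- lapply(g, function(n) ((seq_len(n) - (n + 1) / 2) / (n / 2)))
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  u <- lapply(spec$boundaries, function(b) stats::plogis((b - r) / spec$boundary_width))
  base <- list(GM = u[[2]] - u[[1]],
               WM = u[[1]],
               CSF = u[[3]] - u[[2]],
               bone = u[[4]] - u[[3]],
               soft = u[[5]] - u[[4]],
               background = 1 - u[[5]])
  # interface weights (peak 1 where both memberships are 0.5)
  base$w_gw <- 4 * base$GM * base$WM
  base$w_gc <- 4 * base$GM * base$CSF
  base
}

# Noiseless class probabilities for one demographic setting.
phantom_truth <- function(spec, age_months, male, is3t, base = NULL) {
  if (is.null(base)) base <- phantom_base_maps(spec)
  d_age <- phantom_trajectory(age_months, spec) * base$w_gw
  d_sex <- spec$sex_amp * male * base$w_gc
  d_field <- spec$field_amp * is3t * base$w_gw
  list(GM = base$GM + d_age + d_sex + d_field,
       WM = base$WM - d_age - d_field,
       CSF = base$CSF - d_sex,
       bone = base$bone,
       soft = base$soft,
       background = base$background)
}

#' Generate a phantom cohort with known ground truth
#'
#' Draws demographics per the spec (ages uniform over the range, sexes
#' balanced, field strength Bernoulli, quality indicators Gaussian), builds
#' each subject's six noiseless class volumes, adds per-subject Gaussian
#' noise whose standard deviation decreases with the combined quality
#' indicator, and clamps to `[0, 1]`. Identical seeds give bitwise
#' identical cohorts.
#'
#' @param spec A [phantom_spec()].
#' @return List with `cohort` (a `cohort_table`), `stacks` (named list of
#'   six [tissue_stack()]s), `design` (design matrix), `truth` (base maps,
#'   per-subject noise sigmas, the spec, and a `truth_fun(age, male, is3t)`
#'   closure returning noiseless volumes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_subjects
  g <- spec$grid
  base <- phantom_base_maps(spec)
  out <- with_seed(spec$rng_seed, {
    young <- stats::runif(n) < spec$young_fraction
    ymax <- min(spec$young_max, spec$age_range[2])
    age <- ifelse(young,
                  stats::runif(n, spec$age_range[1], ymax),
                  stats::runif(n, ymax, spec$age_range[2]))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    fs <- sample(c(3, 1.5), n, replace = TRUE,
                 prob = c(spec$prob_3t, 1 - spec$prob_3t))
    resolution <- pmax(stats::rnorm(n, 1.07, 0.12), 0.8)
    cnr <- stats::rnorm(n, 1, 0.15)
    inr <- stats::rnorm(n, 1, 0.15)
    cohort <- cohort_table(data.frame(
      subject_id = sprintf("p%04d", seq_len(n)),
      age_months = age, sex = sex, field_strength = fs,
      resolution = resolution, cnr = cnr, inr = inr,
      stringsAsFactors = FALSE))
    q <- quality_indicator(cohort)
    sigma <- spec$sigma0 * exp(-spec$sigma_quality_slope * q)
    sigma <- pmin(pmax(sigma, spec$sigma0 / 4), spec$sigma0 * 4)

    arrs <- lapply(tissue_classes, function(cl) array(0, c(n, g)))
    names(arrs) <- tissue_classes
    nvox <- prod(g)
    for (i in seq_len(n)) {
      tv <- phantom_truth(spec, age[i], as.numeric(sex[i] == "M"),
                          as.numeric(fs[i] == 3), base)
      for (cl in tissue_classes) {
        v <- tv[[cl]]
        if (sigma[i] > 0) v <- v + stats::rnorm(nvox, 0, sigma[i])
        arrs[[cl]][i, , , ] <- pmin(pmax(v, 0), 1)
      }
    }
    list(cohort = cohort, q = q, sigma = sigma, arrs = arrs)
  })
  stacks <- lapply(tissue_classes, function(cl) {
    tissue_stack(out$arrs[[cl]], cl, voxel_size = spec$voxel_size)
  })
  names(stacks) <- tissue_classes
  design <- build_design_matrix(out$cohort, quality = out$q)
  truth_fun <- function(age_months, male, is3t) {
    phantom_truth(spec, age_months, male, is3t, base)
  }
  list(cohort = out$cohort, stacks = stacks, design = design,
       truth = list(spec = spec, base = base, sigma = out$sigma,
                    quality = out$q, truth_fun = truth_fun))
}

#' Generate a deformation field with analytically known Jacobian
#'
#' @param grid Grid dimensions.
#' @param voxel_size Grid spacing in mm.
#' @param kind `"identity"`, `"uniform_scale"` (scale goes into the affine
#'   slot; displacement zero) or `"sinusoidal"` (displacement
#'   `u_x = amplitude * sin(freq * x_mm)` along x).
#' @param amplitude Sinusoidal displacement amplitude in mm.
#' @param freq Sinusoidal spatial frequency in 1/mm (`amplitude * freq < 1`
#'   keeps the mapping invertible).
#' @param scale Uniform affine scale factor.
#' @return List with `displacement` (4D array, mm), `affine` (4x4),
#'   `jacobian_analytic` (3D array of the closed-form determinant of the
#'   non-affine part) and `kind`.
#' @export
generate_deformation <- function(grid = c(16, 16, 16), voxel_size = c(1, 1, 1),
                                 kind = c("identity", "uniform_scale", "sinusoidal"),
                                 amplitude = 2, freq = 0.1, scale = 1.2) {
  kind <- match.arg(kind)
  disp <- array(0, c(grid, 3))
  affine <- diag(4)
  jac <- array(1, grid)
  if (kind == "uniform_scale") {
    affine <- diag(c(scale, scale, scale, 1))
  } else if (kind == "sinusoidal") {
    stopifnot(abs(amplitude * freq) < 1)
    x_mm <- (seq_len(grid[1]) - 1) * voxel_size[1]
    ux <- amplitude * sin(freq * x_mm)
    disp[, , , 1] <- array(ux, grid)
    jac <- array(1 + amplitude * freq * cos(freq * x_mm), grid)
  }
  list(displacement = disp, affine = affine, jacobian_analytic = jac,
       kind = kind)
}
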