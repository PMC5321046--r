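# Prior-versus-average comparison protocol against a gold standard
# (the overall population mean).

new_metric_report <- function(metric, values, seed, config = list()) {
  structure(list(metric = metric, values = values, seed = seed,
                 config = config), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report [%s], seed %d: %d rows\n",
              x$metric, x$seed, nrow(x$values)))
  invisible(x)
}

#' Write a metric report as JSON (and optionally long-format CSV)
#' @param report A `metric_report`.
#' @param path Output JSON path.
#' @param csv Optional CSV path for the long-format value table.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, csv = NULL) {
  jsonlite::write_json(list(metric = report$metric, seed = report$seed,
                            config = report$config, values = report$values),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(csv)) utils::write.csv(report$values, csv, row.names = FALSE)
  invisible(path)
}

score_against <- function(volume, gold) sum(abs(volume - gold))

# Matched synthetic prior for a subject subset: matched-pairs prediction at
# the subjects' demographics (quality at best available), clipped and
# median-filtered per class.
synthetic_map_for_subset <- function(fit, X, idx, median_radius = 1L) {
  req <- data.frame(age_months = X[idx, "age_months"],
                    sex = X[idx, "sex"],
                    field_strength = X[idx, "field_strength"])
  vol <- predict_priors(list(fit), req)[[1]]
  vol <- clamp01(vol)
  if (median_radius > 0L) vol <- median_filter_3d(vol, median_radius)
  vol
}

#' Compare synthetic priors with plain subgroup averages
#'
#' For each repeat and group size, a random subgroup is drawn from the
#' population; its plain average map (the conventional template) and the
#' matched synthetic prior generated from the subgroup's demographics are
#' both scored by the sum of absolute voxelwise differences against the
#' full-population mean (the gold standard).
#'
#' @param stacks Named list of [tissue_stack()]s (e.g. GM and WM).
#' @param models Named list of matching [fit_voxelwise()] results.
#' @param X Design matrix of the population.
#' @param group_sizes Subgroup sizes to simulate.
#' @param repeats Number of random draws per group size.
#' @param seed Integer seed (all draws are reproducible given it).
#' @param median_radius Median filtering applied to synthetic maps. The
#'   default 0 scores the raw matched-pairs prediction, isolating
#'   modeling-versus-averaging from the post-hoc filtering step (which is
#'   tested separately and remains default-on in [build_priors()]).
#' @return A `metric_report` whose `values` data frame has columns `class`,
#'   `method` (`average`/`synthetic`), `group_size`, `repeat_id`,
#'   `disagreement`.
#' @export
compare_to_gold_standard <- function(stacks, models, X,
                                     group_sizes = c(25, 50, 100),
                                     repeats = 100L, seed = 1L,
                                     median_radius = 0L) {
  stopifnot(length(stacks) >= 1L, all(names(stacks) %in% names(models)))
  n <- stack_n_subjects(stacks[[1]])
  if (any(group_sizes > n)) stop("group size exceeds population size")
  gold <- lapply(stacks, stack_mean)
  rows <- list()
  with_seed(seed, {
    for (gs in group_sizes) {
      for (r in seq_len(repeats)) {
        idx <- sample.int(n, gs)
        for (cl in names(stacks)) {
          avg <- subset_mean(stacks[[cl]]$data, idx)
          synth <- synthetic_map_for_subset(models[[cl]], X, idx, median_radius)
          rows[[length(rows) + 1L]] <-
            data.frame(class = cl,
                       method = c("average", "synthetic"),
                       group_size = gs, repeat_id = r,
                       disagreement = c(score_against(avg, gold[[cl]]),
                                        score_against(synth, gold[[cl]])))
        }
      }
    }
  })
  new_metric_report("gold_standard_comparison", do.call(rbind, rows), seed,
                    config = list(group_sizes = group_sizes, repeats = repeats,
                                  median_radius = median_radius))
}

#' Disagreement of matched priors as the population shrinks
#'
#' The population is shuffled once (seeded) and iteratively shrunk in steps;
#' at each size, matched synthetic priors for random subgroups of
#' `subgroup_n` subjects are scored against that population's mean map.
#'
#' @param stacks,models,X As in [compare_to_gold_standard()].
#' @param subgroup_n Subgroup size driving each synthetic prior.
#' @param repeats Random subgroups per population size.
#' @param step Population-size decrement.
#' @param min_n Smallest population size retained.
#' @param seed Integer seed.
#' @param median_radius Median filtering applied to synthetic maps.
#' @return A `metric_report` with columns `class`, `population_size`,
#'   `repeat_id`, `disagreement`.
#' @export
shrinking_population_curve <- function(stacks, models, X, subgroup_n = 25L,
                                       repeats = 10L, step = 25L,
                                       min_n = 2L * subgroup_n, seed = 1L,
                                       median_radius = 0L) {
  n <- stack_n_subjects(stacks[[1]])
  if (n < max(subgroup_n, min_n)) stop("population smaller than the minimum size")
  sizes <- seq(n, max(subgroup_n, min_n), by = -step)
  rows <- list()
  with_seed(seed, {
    shuffle <- sample.int(n)
    for (sz in sizes) {
      pop <- shuffle[seq_len(sz)]
      for (cl in names(stacks)) {
        popmean <- subset_mean(stacks[[cl]]$data, pop)
        for (r in seq_len(repeats)) {
          idx <- pop[sample.int(sz, subgroup_n)]
          synth <- synthetic_map_for_subset(models[[cl]], X, idx, median_radius)
          rows[[length(rows) + 1L]] <-
            data.frame(class = cl, population_size = sz, repeat_id = r,
                       disagreement = score_against(synth, popmean))
        }
      }
    }
  })
  new_metric_report("shrinking_population", do.call(rbind, rows), seed,
                    config = list(subgroup_n = subgroup_n, repeats = repeats,
                                  step = step, median_radius = median_radius))
}
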