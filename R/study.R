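#' Bundled multi-site study demographics
#'
#' Loads the packaged per-dataset demographic summary (four public MRI
#' cohorts pooled for lifespan template construction: NIH, C-MIND, fCONN,
#' IXI) and derives the pooled counts and the quality-screening rejection
#' percentage.
#'
#' @param path Optional path to an alternative summary JSON.
#' @return List with `datasets` (data frame), `initial_n`, `final_n`,
#'   `pooled` (named vector: males, females, n_3t, n_15t) and
#'   `rejection_pct` (percent of initially screened images excluded).
#' @export
study_cohort_summary <- function(path = system.file("extdata", "study_cohort.json",
                                                    package = "tpmars")) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ds <- as.data.frame(obj$datasets)
  final_n <- sum(ds$n)
  pooled <- c(males = sum(ds$males), females = sum(ds$females),
              n_3t = sum(ds$n_3t), n_15t = sum(ds$n_15t))
  list(datasets = ds,
       initial_n = obj$initial_n,
       final_n = final_n,
       pooled = pooled,
       rejection_pct = 100 * (obj$initial_n - final_n) / obj$initial_n)
}
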