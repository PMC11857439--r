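#' Run the normative-model workflow for a set of regions
#'
#' Splits the cohort into balanced train/test halves, fits the warped-BLR
#' normative model of uptake against age on the training half of each
#' region, then scores every subject (train and test) with deviation
#' Z-scores, computes the test-half explained variance of the
#' back-transformed median predictions, and evaluates centile curves over
#' an age grid.
#'
#' @param roi_table Subjects-by-regions uptake tibble.
#' @param cohort Cohort tibble.
#' @param regions Character vector of regions to model; default every
#'   region column.
#' @param seed Integer seed (drives the stratified split).
#' @param age_grid Evaluation grid for the centile curves.
#' @param quantiles Centile levels, see [centiles()].
#' @return An object of class `normative_run`: list with `models` (named
#'   list of `normative_model`), `deviations` (per-subject tibble with
#'   `half` tags), `ev` (per-region test-half EV), `centiles` (long curve
#'   tibble) and `split` (the tagged cohort).
#' @export
run_normative <- function(roi_table, cohort, regions = NULL, seed,
                          age_grid = seq(20, 81, by = 0.5),
                          quantiles = c(0.01, 0.05, 0.25, 0.50, 0.75,
                                        0.95, 0.99)) {
  if (missing(seed)) abort("`seed` is required")
  regions <- regions %||% setdiff(names(roi_table), "subject_id")
  missing_r <- setdiff(regions, names(roi_table))
  if (length(missing_r)) {
    abort(paste0("region(s) not in `roi_table`: ",
                 paste(missing_r, collapse = ", ")))
  }
  tagged <- stratified_half_split(cohort, seed = seed)
  dat <- dplyr::inner_join(tagged, roi_table, by = "subject_id")
  train <- dplyr::filter(dat, .data$half == "train")
  test <- dplyr::filter(dat, .data$half == "test")

  models <- list(); devs <- list(); evs <- list(); cents <- list()
  for (reg in regions) {
    fit <- fit_normative(train$age, train[[reg]])
    models[[reg]] <- fit
    dv <- zscores(fit, dat$age, dat[[reg]], subject_id = dat$subject_id)
    dv$region <- reg
    dv$half <- dat$half
    devs[[reg]] <- dv
    pr_test <- suppressWarnings(predict(fit, test$age))
    evs[[reg]] <- tibble::tibble(
      region = reg,
      ev_test = explained_variance(test[[reg]], pr_test$median_pred),
      n_train = nrow(train), n_test = nrow(test)
    )
    cc <- suppressWarnings(centiles(fit, age_grid, quantiles = quantiles))
    cc$region <- reg
    cents[[reg]] <- cc
  }
  structure(
    list(models = models,
         deviations = dplyr::bind_rows(devs),
         ev = dplyr::bind_rows(evs),
         centiles = dplyr::bind_rows(cents),
         split = tagged, seed = seed),
    class = "normative_run"
  )
}

#' @export
print.normative_run <- function(x, ...) {
  cat("<normative_run>", length(x$models), "region(s);",
      sum(x$split$half == "train"), "train /",
      sum(x$split$half == "test"), "test subjects\n")
  print(x$ev)
  invisible(x)
}

#' @export
tidy.normative_run <- function(x, ...) x$deviations

#' @export
glance.normative_run <- function(x, ...) {
  dplyr::bind_cols(
    x$ev,
    purrr::map_dfr(x$models, glance)[, c("alpha", "beta", "warp_a",
                                         "warp_b", "nlml")]
  )
}
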