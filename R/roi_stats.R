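#' Pearson correlation of regional uptake with age
#'
#' Correlates each region's uptake with age across subjects, with two-sided
#' p-values from the t transform on n - 2 degrees of freedom and Bonferroni
#' correction over `m` regions (`p_bonf = min(1, m * p)`). The default
#' `m = 4` reflects the four striatal regions tested.
#'
#' @param roi_table Tibble with `subject_id` and one column per region.
#' @param cohort Cohort tibble with `subject_id`, `age`, `sex`.
#' @param regions Regions to test; default every non-id column.
#' @param m Number of comparisons for Bonferroni.
#' @param stratum Tag recorded in the output (`"all"`, `"male"`, `"female"`).
#' @return Tibble: `region`, `stratum`, `n`, `r`, `p`, `p_bonf`.
#' @export
pearson_age_correlation <- function(roi_table, cohort, regions = NULL,
                                    m = 4L, stratum = "all") {
  if (m < 1L) abort("`m` must be >= 1")
  regions <- regions %||% setdiff(names(roi_table), "subject_id")
  dat <- dplyr::inner_join(cohort, roi_table, by = "subject_id")
  n <- nrow(dat)
  if (n < 3L) abort("need at least 3 subjects for a correlation")
  purrr::map_dfr(regions, function(reg) {
    y <- dat[[reg]]
    if (is.null(y)) abort(paste0("region '", reg, "' not in `roi_table`"))
    if (var(dat$age) == 0 || var(y) == 0) {
      abort(paste0("zero variance in region '", reg, "' or in age"))
    }
    ct <- cor.test(dat$age, y, method = "pearson",
                   alternative = "two.sided")
    tibble::tibble(
      region = reg, stratum = stratum, n = n,
      r = unname(ct$estimate), p = ct$p.value,
      p_bonf = min(1, m * ct$p.value)
    )
  })
}

#' Sex-stratified age correlations
#'
#' Repeats [pearson_age_correlation()] separately within the male and
#' female strata.
#'
#' @inheritParams pearson_age_correlation
#' @return Tibble with one row per region and stratum.
#' @export
sex_stratified_correlation <- function(roi_table, cohort, regions = NULL,
                                       m = 4L) {
  purrr::map_dfr(c("male", "female"), function(s) {
    sub <- dplyr::filter(cohort, .data$sex == s)
    if (nrow(sub) < 3L) {
      abort(sprintf("stratum '%s' has fewer than 3 subjects", s))
    }
    pearson_age_correlation(roi_table, sub, regions = regions, m = m,
                            stratum = s)
  })
}
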