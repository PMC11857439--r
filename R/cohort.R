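#' Age-decade by sex margins of the reference cohort
#'
#' Cell counts of the 116-subject healthy reference sample: 77 males and 39
#' females aged 20 to 81, tabulated in decade bins.
#'
#' @return A tibble with columns `sex`, `age_lo`, `age_hi`, `n`.
#' @export
cohort_margins <- function() {
  bins_lo <- c(20, 31, 41, 51, 61, 71)
  bins_hi <- c(30, 40, 50, 60, 70, 81)
  tibble::tibble(
    sex    = rep(c("male", "female"), each = 6L),
    age_lo = rep(bins_lo, 2L),
    age_hi = rep(bins_hi, 2L),
    n      = c(2L, 14L, 18L, 18L, 20L, 5L,
               0L, 9L, 16L, 11L, 3L, 0L)
  )
}

#' Generate a synthetic cohort table
#'
#' Draws a cohort of subjects whose age-decade by sex cell counts follow the
#' supplied margins (by default the 116-subject reference sample: 77 male,
#' 39 female, ages 20-81). Ages are drawn uniformly within each decade bin,
#' which is the weakest assumption consistent with binned counts.
#'
#' @param n Expected total number of subjects; must equal `sum(margins$n)`.
#' @param margins Margins tibble as returned by [cohort_margins()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with columns `subject_id`, `age`, `sex`.
#' @examples
#' co <- generate_cohort(seed = 1)
#' table(co$sex)
#' @export
generate_cohort <- function(n = NULL, margins = cohort_margins(), seed) {
  if (missing(seed)) abort("`seed` is required for reproducible generation")
  req <- c("sex", "age_lo", "age_hi", "n")
  if (!all(req %in% names(margins))) {
    abort("`margins` must have columns sex, age_lo, age_hi, n")
  }
  total <- sum(margins$n)
  if (!is.null(n) && n != total) {
    abort(sprintf(
      "requested total n = %d is inconsistent with margins (sum = %d)",
      n, total
    ))
  }
  if (any(margins$age_hi < margins$age_lo) || any(margins$n < 0)) {
    abort("malformed margins: need age_hi >= age_lo and n >= 0")
  }
  withr::with_seed(seed, {
    ages <- purrr::pmap(margins, function(sex, age_lo, age_hi, n) {
      runif(n, min = age_lo, max = age_hi)
    })
    out <- tibble::tibble(
      age = unlist(ages),
      sex = rep(margins$sex, margins$n)
    )
  })
  out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
  dplyr::select(out, "subject_id", "age", "sex")
}
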