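#' Stratified half split of a cohort
#'
#' Splits the cohort into train and test halves of equal size with sex and
#' age balanced across the halves: within each sex, subjects are sorted by
#' age and assigned alternately to the two halves. The alternation phase is
#' randomized by the seed; phases of odd-sized strata are paired off so the
#' overall halves come out exactly `n/2` each (for even `n`; odd `n` gives
#' halves differing by one).
#'
#' @param cohort Cohort tibble with `subject_id`, `age`, `sex`.
#' @param seed Integer seed.
#' @return The cohort tibble with an added `half` column
#'   (`"train"`/`"test"`).
#' @examples
#' co <- generate_cohort(seed = 1)
#' table(stratified_half_split(co, seed = 2)$half)
#' @export
stratified_half_split <- function(cohort, seed) {
  if (missing(seed)) abort("`seed` is required")
  strata <- split(cohort, cohort$sex)
  odd <- vapply(strata, function(s) nrow(s) %% 2L == 1L, logical(1))
  withr::with_seed(seed, {
    phases <- vapply(strata, function(s) sample(0:1, 1L), integer(1))
    # pair odd strata with alternating phases so the totals balance
    if (sum(odd) > 1L) {
      p0 <- sample(0:1, 1L)
      phases[odd] <- (p0 + seq_len(sum(odd)) - 1L) %% 2L
    }
  })
  out <- purrr::imap(strata, function(s, sx) {
    s <- dplyr::arrange(s, .data$age)
    idx <- (seq_len(nrow(s)) + phases[[sx]]) %% 2L
    s$half <- ifelse(idx == 1L, "train", "test")
    s
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$subject_id)
}
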