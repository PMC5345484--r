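# Published reference cohort summary.
#
# The package ships the site-stratified summary of a published institutional
# reference cohort: 711 VMAT plans (2013 to mid-2015) that went through
# pretreatment QA, of which 62 failed, summarised at a complexity threshold
# of 0.18 1/mm.  The per-plan scores are not public, so only the printed
# counts and moments are available; they anchor the default threshold and
# the contingency arithmetic the tests verify.

#' Reference cohort summary table
#'
#' Site-stratified counts and complexity moments of the institutional
#' reference cohort at a threshold of 0.18 1/mm.  Columns match
#' [cohort_summary()] output: `group`, `total`, `failing`, `above`,
#' `failing_above`, `mean_pass`, `sd_pass`, `mean_fail`, `sd_fail`.
#'
#' @return data.frame with one row per site group plus the "All" row
#' @export
reference_cohort_summary <- function() {
  path <- system.file("extdata", "reference_cohort_summary.csv",
                      package = "vmatqa", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' The complexity threshold the reference summary was tabulated at
#' @return 0.18 (1/mm)
#' @export
reference_threshold <- function() 0.18

#' Group shares within a cohort summary
#'
#' Derived proportions for a set of groups in a [cohort_summary()]-shaped
#' table: the groups' share of all plans, their share of all failing plans,
#' and the fraction of the groups' own plans above the threshold.
#'
#' @param summary a summary data.frame (e.g. [reference_cohort_summary()]);
#'   must contain an "All" row
#' @param groups character vector of group labels to pool
#' @return list with fractions `share_of_plans`, `share_of_failing`,
#'   `frac_above_threshold`
#' @export
summary_group_shares <- function(summary, groups) {
  all_row <- summary[summary$group == "All", , drop = FALSE]
  if (nrow(all_row) != 1L) abort("summary must contain exactly one 'All' row")
  g <- summary[summary$group %in% groups, , drop = FALSE]
  if (nrow(g) != length(groups)) {
    abort("group(s) not found in summary: ",
          paste(setdiff(groups, summary$group), collapse = ", "))
  }
  list(
    share_of_plans = sum(g$total) / all_row$total,
    share_of_failing = sum(g$failing) / all_row$failing,
    frac_above_threshold = sum(g$above) / sum(g$total)
  )
}

#' Labeled cohort reconstructed from the reference contingency counts
#'
#' Uses the "All" row of the reference summary to rebuild a minimal labeled
#' cohort with the published above/below-threshold counts (see
#' [cohort_from_counts()]), enough to reproduce the published TPR/FPR at the
#' reference threshold but not the underlying score distribution.
#'
#' @return cohort data.frame
#' @export
reference_contingency_cohort <- function() {
  s <- reference_cohort_summary()
  all_row <- s[s$group == "All", ]
  cohort_from_counts(
    threshold = reference_threshold(),
    fail_above = all_row$failing_above,
    fail_below = all_row$failing - all_row$failing_above,
    pass_above = all_row$above - all_row$failing_above,
    pass_below = (all_row$total - all_row$failing) -
      (all_row$above - all_row$failing_above)
  )
}
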