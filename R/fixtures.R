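## Published change-count margins from the pediatric rheumatology
## decision-support study this package's evaluation framework models:
## 26 testers (Table 1 mix) by 8 case vignettes, counts of baseline
## diagnostic errors, errors fixed by decision support, and errors added.

#' Change-count margins by tester group
#'
#' Baseline/fixed/added diagnostic error counts per specialty-by-seniority
#' tester group, with the study's tester mix (5/5/3 junior and 5/4/4 senior
#' rheumatology/emergency/pediatrics testers; 8 cases each). Feed to
#' \code{\link{buildFixtureLog}(layout = "by_group")} to reconstruct a
#' response log reproducing the published group table.
#'
#' @return data.frame with columns specialty, seniority, n_testers,
#'   baseline_errors, fixed_errors, added_errors.
#' @examples
#' fx <- buildFixtureLog(table4Margins(), layout = "by_group")
#' aggregateChanges(fx$log, fx$gold, group_by = "specialty")
#' @export
table4Margins <- function() {
  data.frame(
    specialty = rep(c("rheumatology", "emergency", "pediatrics"), 2),
    seniority = rep(c("junior", "senior"), each = 3),
    n_testers = c(5L, 5L, 3L, 5L, 4L, 4L),
    baseline_errors = c(5L, 13L, 8L, 4L, 13L, 15L),
    fixed_errors = c(4L, 10L, 6L, 1L, 8L, 4L),
    added_errors = c(0L, 0L, 2L, 0L, 2L, 3L))
}

#' Change-count margins by case
#'
#' Baseline/fixed/added diagnostic error counts per case vignette (26
#' testers sit every case). Feed to
#' \code{\link{buildFixtureLog}(layout = "by_case")} to reconstruct a
#' response log reproducing the published per-case table.
#'
#' @return data.frame with columns case_id, baseline_errors, fixed_errors,
#'   added_errors.
#' @examples
#' fx <- buildFixtureLog(table5Margins(), layout = "by_case")
#' aggregateChanges(fx$log, fx$gold, group_by = "case")
#' @export
table5Margins <- function() {
  data.frame(
    case_id = c("1184", "6295", "3613", "2088", "8434", "7870", "5615",
                "4967"),
    baseline_errors = c(19L, 15L, 8L, 4L, 4L, 3L, 3L, 2L),
    fixed_errors = c(8L, 10L, 3L, 3L, 3L, 2L, 3L, 1L),
    added_errors = c(1L, 0L, 2L, 0L, 0L, 1L, 2L, 1L))
}
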