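## Study evaluation framework: diagnostic error and relevance against gold
## standards, before/after change classification, grouped aggregation tables
## in the printed-table style (integer percentages, half-up rounding), and
## construction of synthetic response logs matching published table margins.
##
## A response log is a data.frame with one row per (tester, case, phase):
## columns tester_id, specialty, seniority, case_id, phase
## ("baseline"/"aided"), differential and workup (semicolon-separated ids).
## Gold standards are a list of records with fields case_id,
## correct_diagnosis, correct_categories, gold_differential, gold_workup.

.splitIds <- function(x) {
  if (length(x) == 1L && is.character(x) && grepl(";", x, fixed = TRUE))
    x <- strsplit(x, ";", fixed = TRUE)[[1]]
  x <- trimws(as.character(x))
  tolower(x[nzchar(x)])
}

.goldFor <- function(gold, case_id) {
  for (g in gold) if (g$case_id == case_id) return(g)
  stop(sprintf("no gold standard for case '%s'", case_id))
}

#' Diagnostic error of a response
#'
#' A response is a diagnostic error when its differential contains neither
#' the correct diagnosis nor any of its categories. Matching is by
#' identifier equality after case-insensitive normalization.
#'
#' @param record a list or one-row data.frame with fields case_id and
#'   differential (character vector or semicolon-separated string).
#' @param gold the gold-standard record for the same case (fields case_id,
#'   correct_diagnosis, correct_categories).
#' @return TRUE iff the response is a diagnostic error.
#' @examples
#' gold <- list(case_id = "c1", correct_diagnosis = "dx_a",
#'              correct_categories = "cat_a",
#'              gold_differential = c("dx_a", "dx_b"))
#' isError(list(case_id = "c1", differential = "dx_x;cat_a"), gold)  # FALSE
#' @export
isError <- function(record, gold) {
  if (record$case_id != gold$case_id)
    stop(sprintf("case mismatch: record '%s' vs gold '%s'",
                 record$case_id, gold$case_id))
  dd <- .splitIds(record$differential)
  hits <- c(tolower(gold$correct_diagnosis),
            tolower(unlist(gold$correct_categories)))
  !any(dd %in% hits)
}

#' Relevance of a response
#'
#' Fraction of the diagnoses in the tester's differential that also appear
#' in the gold-standard differential.
#'
#' @inheritParams isError
#' @return A number in [0, 1].
#' @examples
#' gold <- list(case_id = "c1", correct_diagnosis = "dx_a",
#'              correct_categories = character(),
#'              gold_differential = c("dx_a", "dx_b"))
#' relevance(list(case_id = "c1", differential = "dx_a;dx_x;dx_y;dx_z"),
#'           gold)  # 0.25
#' @export
relevance <- function(record, gold) {
  if (record$case_id != gold$case_id)
    stop(sprintf("case mismatch: record '%s' vs gold '%s'",
                 record$case_id, gold$case_id))
  dd <- .splitIds(record$differential)
  if (!length(dd)) stop("empty differential")
  mean(dd %in% tolower(unlist(gold$gold_differential)))
}

#' Classify the change between baseline and aided responses
#'
#' @param baseline,aided the two responses of one tester on one case
#'   (phases "baseline" and "aided").
#' @param gold the case's gold standard.
#' @return One of "fixed_error" (error became correct), "added_error"
#'   (correct became error), "unchanged_correct", "unchanged_error".
#' @export
classifyChange <- function(baseline, aided, gold) {
  if (baseline$tester_id != aided$tester_id ||
      baseline$case_id != aided$case_id)
    stop("baseline and aided records must share tester and case")
  if (!identical(as.character(baseline$phase), "baseline") ||
      !identical(as.character(aided$phase), "aided"))
    stop("records must carry phases 'baseline' and 'aided'")
  e0 <- isError(baseline, gold)
  e1 <- isError(aided, gold)
  if (e0 && !e1) "fixed_error"
  else if (!e0 && e1) "added_error"
  else if (e0) "unchanged_error"
  else "unchanged_correct"
}

## one row per tester-case pair with error flags and change class
.pairTable <- function(log, gold) {
  b <- log[log$phase == "baseline", , drop = FALSE]
  a <- log[log$phase == "aided", , drop = FALSE]
  key_b <- paste(b$tester_id, b$case_id)
  key_a <- paste(a$tester_id, a$case_id)
  if (anyDuplicated(key_b) || anyDuplicated(key_a))
    stop("duplicate (tester_id, case_id, phase) in response log")
  if (!setequal(key_b, key_a))
    stop("unpaired baseline/aided records in response log")
  a <- a[match(key_b, key_a), , drop = FALSE]
  n <- nrow(b)
  err_b <- logical(n); err_a <- logical(n)
  len_b <- integer(n); len_a <- integer(n)
  for (i in seq_len(n)) {
    g <- .goldFor(gold, b$case_id[i])
    err_b[i] <- isError(as.list(b[i, ]), g)
    err_a[i] <- isError(as.list(a[i, ]), g)
    len_b[i] <- length(.splitIds(b$differential[i]))
    len_a[i] <- length(.splitIds(a$differential[i]))
  }
  cls <- ifelse(err_b & !err_a, "fixed_error",
                ifelse(!err_b & err_a, "added_error",
                       ifelse(err_b, "unchanged_error",
                              "unchanged_correct")))
  data.frame(tester_id = b$tester_id, specialty = b$specialty,
             seniority = b$seniority, case_id = b$case_id,
             baseline_error = err_b, aided_error = err_a, change = cls,
             baseline_len = len_b, aided_len = len_a)
}

#' Aggregate change counts into a printed-style table
#'
#' Pairs baseline and aided responses per tester and case, classifies each
#' change, and tabulates counts and integer percentages per group:
#' baseline/fixed/added error counts, aided errors (baseline - fixed +
#' added), percent of changes that reduced errors (blank when no changes),
#' baseline and aided error rates over the group's testing instances, and
#' the relative decrease in errors. Percentages are rounded half-up to whole
#' percent, matching the printed-table style.
#'
#' @param log a response log data.frame (see \code{\link{readResponseLog}}).
#' @param gold list of gold-standard records.
#' @param group_by "all", "tester", "case", or any subset of
#'   c("specialty", "seniority").
#' @return data.frame with the grouping column(s) and columns instances,
#'   baseline_errors, fixed_errors, added_errors, aided_errors,
#'   pct_changes_improving, baseline_error_rate_pct, aided_error_rate_pct,
#'   relative_decrease_pct.
#' @examples
#' fx <- buildFixtureLog(table4Margins(), layout = "by_group")
#' aggregateChanges(fx$log, fx$gold, group_by = "all")
#' @export
aggregateChanges <- function(log, gold, group_by = "all") {
  pairs <- .pairTable(log, gold)
  cols <- switch(paste(sort(group_by), collapse = "+"),
                 all = NULL, tester = "tester_id", case = "case_id",
                 specialty = "specialty", seniority = "seniority",
                 `seniority+specialty` = c("specialty", "seniority"),
                 stop(sprintf("unknown group_by: %s",
                              paste(group_by, collapse = ", "))))
  key <- if (is.null(cols)) rep("all", nrow(pairs)) else
    do.call(paste, c(pairs[cols], sep = "\r"))
  groups <- split(pairs, key)
  rows <- lapply(groups, function(g) {
    fixed <- sum(g$change == "fixed_error")
    added <- sum(g$change == "added_error")
    base_err <- sum(g$baseline_error)
    aided_err <- base_err - fixed + added
    n <- nrow(g)
    out <- data.frame(
      instances = n, baseline_errors = base_err, fixed_errors = fixed,
      added_errors = added, aided_errors = aided_err,
      pct_changes_improving = if (fixed + added > 0)
        .roundHalfUp(100 * fixed / (fixed + added)) else NA_real_,
      baseline_error_rate_pct = .roundHalfUp(100 * base_err / n),
      aided_error_rate_pct = .roundHalfUp(100 * aided_err / n),
      relative_decrease_pct = if (base_err > 0)
        .roundHalfUp(100 * (base_err - aided_err) / base_err) else NA_real_)
    if (!is.null(cols))
      out <- cbind(g[1, cols, drop = FALSE], out)
    else out <- cbind(data.frame(group = "all"), out)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential-list size by change stratum
#'
#' Mean and median number of entries in the differential, per phase, for all
#' tester-case pairs and for the "unchanged correct" and "fixed error"
#' strata.
#'
#' @inheritParams aggregateChanges
#' @return data.frame with columns stratum, n, baseline_mean,
#'   baseline_median, aided_mean, aided_median.
#' @export
differentialSizeStats <- function(log, gold) {
  pairs <- .pairTable(log, gold)
  strata <- list(all = pairs,
                 unchanged_correct =
                   pairs[pairs$change == "unchanged_correct", ],
                 fixed_error = pairs[pairs$change == "fixed_error", ])
  rows <- lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    data.frame(stratum = nm, n = nrow(s),
               baseline_mean = mean(s$baseline_len),
               baseline_median = stats::median(s$baseline_len),
               aided_mean = mean(s$aided_len),
               aided_median = stats::median(s$aided_len))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- response log / gold standard I/O ------------------------------------

#' Read and write response logs and gold standards
#'
#' Response logs are TSV files with columns tester_id, specialty, seniority,
#' case_id, phase, differential, workup (the last two semicolon-separated id
#' lists). Gold standards are a JSON array of objects with fields case_id,
#' correct_diagnosis, correct_categories, gold_differential, gold_workup.
#'
#' @param path file path.
#' @return \code{readResponseLog}: the log data.frame;
#'   \code{readGoldStandards}: a list of gold records.
#' @name response-io
NULL

#' @rdname response-io
#' @export
readResponseLog <- function(path) {
  log <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  need <- c("tester_id", "specialty", "seniority", "case_id", "phase",
            "differential")
  missing <- setdiff(need, names(log))
  if (length(missing))
    stop(sprintf("response log lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (!"workup" %in% names(log)) log$workup <- ""
  log
}

#' @rdname response-io
#' @param log a response log data.frame.
#' @export
writeResponseLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname response-io
#' @export
readGoldStandards <- function(path) {
  gl <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(gl, function(g) {
    g$correct_categories <- as.character(unlist(g$correct_categories))
    g$gold_differential <- as.character(unlist(g$gold_differential))
    g$gold_workup <- as.character(unlist(g$gold_workup))
    if (length(g$gold_differential) &&
        tolower(g$gold_differential[1]) != tolower(g$correct_diagnosis))
      stop(sprintf(
        "gold standard for case '%s': correct diagnosis must rank #1",
        g$case_id))
    g
  })
}

#' @rdname response-io
#' @param gold a list of gold-standard records.
#' @export
writeGoldStandards <- function(gold, path) {
  writeLines(jsonlite::toJSON(gold, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

## ---- fixture log construction --------------------------------------------

## default roster: 26 testers in the study's specialty/seniority mix
.defaultRoster <- function() {
  data.frame(
    tester_id = sprintf("t%02d", 1:26),
    specialty = c(rep("rheumatology", 5), rep("emergency", 5),
                  rep("pediatrics", 3),
                  rep("rheumatology", 5), rep("emergency", 4),
                  rep("pediatrics", 4)),
    seniority = c(rep("junior", 13), rep("senior", 13)))
}

.FIXTURE_CASES <- c("1184", "2088", "3613", "4967", "5615", "6295", "7870",
                    "8434")

.fixtureGold <- function(cases = .FIXTURE_CASES) {
  lapply(cases, function(cs) list(
    case_id = cs,
    correct_diagnosis = paste0("dx_", cs),
    correct_categories = paste0("cat_", cs),
    gold_differential = c(paste0("dx_", cs), paste0("dx_", cs, "_alt")),
    gold_workup = paste0("test_", cs)))
}

## differential strings for a correct / erroneous response on a case
.correctDiff <- function(cs) paste0("dx_", cs, ";dx_distractor")
.errorDiff <- function(cs) "dx_miss_a;dx_miss_b"

#' Build a synthetic response log matching published table margins
#'
#' Constructs a deterministic 26-tester by 8-case by 2-phase response log
#' whose per-group (or per-case) counts of baseline errors, fixed errors and
#' added errors equal the supplied margins, together with a matching set of
#' synthetic gold standards. Error instances are allocated greedily in
#' tester-id then case-id order: within each margin row the first
#' \code{baseline_errors} instances are baseline errors, the first
#' \code{fixed_errors} of those become correct in the aided phase, and the
#' next \code{added_errors} correct instances become aided errors.
#'
#' @param margins for \code{layout = "by_group"}: data.frame with columns
#'   specialty, seniority, n_testers, baseline_errors, fixed_errors,
#'   added_errors (one row per tester group). For \code{layout = "by_case"}:
#'   columns case_id, baseline_errors, fixed_errors, added_errors (one row
#'   per case; all 26 testers sit each case).
#' @param layout "by_group" or "by_case".
#' @return list with elements \code{log} (response log data.frame) and
#'   \code{gold} (list of gold-standard records).
#' @seealso \code{\link{table4Margins}}, \code{\link{table5Margins}}
#' @examples
#' fx <- buildFixtureLog(table5Margins(), layout = "by_case")
#' aggregateChanges(fx$log, fx$gold, group_by = "case")
#' @export
buildFixtureLog <- function(margins, layout = c("by_group", "by_case")) {
  layout <- match.arg(layout)
  cases <- .FIXTURE_CASES
  gold <- .fixtureGold(cases)

  if (layout == "by_group") {
    need <- c("specialty", "seniority", "n_testers", "baseline_errors",
              "fixed_errors", "added_errors")
  } else {
    need <- c("case_id", "baseline_errors", "fixed_errors", "added_errors")
  }
  missing <- setdiff(need, names(margins))
  if (length(missing))
    stop(sprintf("margins lack column(s): %s",
                 paste(missing, collapse = ", ")))

  blocks <- list()
  if (layout == "by_group") {
    tester_no <- 0L
    for (r in seq_len(nrow(margins))) {
      m <- margins[r, ]
      ids <- sprintf("t%02d", tester_no + seq_len(m$n_testers))
      tester_no <- tester_no + m$n_testers
      inst <- expand.grid(case_id = cases, tester_id = ids,
                          stringsAsFactors = FALSE)
      inst <- inst[order(inst$tester_id, inst$case_id), , drop = FALSE]
      n <- nrow(inst)
      .checkMargins(m, n, sprintf("%s/%s", m$specialty, m$seniority))
      inst$specialty <- m$specialty
      inst$seniority <- m$seniority
      blocks[[r]] <- .allocateFlags(inst, m$baseline_errors,
                                    m$fixed_errors, m$added_errors)
    }
  } else {
    roster <- .defaultRoster()
    if (!setequal(margins$case_id, cases))
      stop("by_case margins must cover exactly the eight study cases")
    for (r in seq_len(nrow(margins))) {
      m <- margins[r, ]
      inst <- roster
      inst$case_id <- m$case_id
      n <- nrow(inst)
      .checkMargins(m, n, sprintf("case %s", m$case_id))
      blocks[[r]] <- .allocateFlags(inst, m$baseline_errors,
                                    m$fixed_errors, m$added_errors)
    }
  }
  inst <- do.call(rbind, blocks)

  mk <- function(phase, err) {
    data.frame(tester_id = inst$tester_id, specialty = inst$specialty,
               seniority = inst$seniority, case_id = inst$case_id,
               phase = phase,
               differential = ifelse(err, .errorDiff(inst$case_id),
                                     .correctDiff(inst$case_id)),
               workup = paste0("test_", inst$case_id))
  }
  log <- rbind(mk("baseline", inst$baseline_error),
               mk("aided", inst$aided_error))
  log <- log[order(log$tester_id, log$case_id, log$phase), , drop = FALSE]
  rownames(log) <- NULL
  list(log = log, gold = gold)
}

.checkMargins <- function(m, n, label) {
  if (m$fixed_errors > m$baseline_errors)
    stop(sprintf("inconsistent margins for %s: fixed_errors (%d) > baseline_errors (%d)",
                 label, m$fixed_errors, m$baseline_errors))
  if (m$baseline_errors + m$added_errors > n)
    stop(sprintf("inconsistent margins for %s: baseline_errors + added_errors exceed %d instances",
                 label, n))
  if (m$baseline_errors < 0 || m$fixed_errors < 0 || m$added_errors < 0)
    stop(sprintf("inconsistent margins for %s: negative count", label))
}

.allocateFlags <- function(inst, n_base, n_fixed, n_added) {
  n <- nrow(inst)
  base <- seq_len(n) <= n_base
  aided <- base
  aided[seq_len(n) <= n_fixed] <- FALSE                 # fixed errors
  aided[n_base + seq_len(n_added)] <- TRUE              # added errors
  inst$baseline_error <- base
  inst$aided_error <- aided
  inst
}
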