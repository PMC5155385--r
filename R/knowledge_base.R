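## Knowledge-base I/O, validation and the curation completeness audit.
##
## On disk a KB is a single JSON document with top-level keys "findings",
## "diseases", "associations", "categories", "core_checklist"
## (schema: inst/extdata/kb-schema.json). Serialization is canonical —
## records sorted by id — so save/load round-trips are byte-identical.

#' Read a knowledge base from a JSON file
#'
#' @param path path to a KB JSON document.
#' @return A validated \code{\link{KnowledgeBase}}.
#' @details The file must validate: any curation-rule violation found by
#'   \code{\link{validateKB}} aborts the load with a message naming the
#'   offending record(s).
#' @examples
#' f <- tempfile(fileext = ".json")
#' saveKB(toyKB(), f)
#' kb <- loadKB(f)
#' @seealso \code{\link{saveKB}}, \code{\link{validateKB}}
#' @export
loadKB <- function(path) {
  if (!file.exists(path))
    stop(sprintf("knowledge base file not found: '%s'", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e)
      stop(sprintf("parse error in '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
  kb <- .kbFromList(doc)
  viol <- validateKB(kb)
  if (nrow(viol))
    stop(sprintf("invalid knowledge base '%s':\n%s", path,
                 paste(sprintf("  [%s %s] %s", viol$entity_type,
                               viol$entity_id, viol$message),
                       collapse = "\n")), call. = FALSE)
  kb
}

#' Write a knowledge base to a JSON file
#'
#' Writes the canonical JSON serialization (records sorted by id, full
#' numeric precision), so that identical knowledge bases produce
#' byte-identical files.
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveKB <- function(kb, path) {
  writeLines(kbToJSON(kb), path, useBytes = TRUE)
  invisible(path)
}

#' Canonical JSON serialization of a knowledge base
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @return A single JSON string.
#' @export
kbToJSON <- function(kb) {
  fd <- kb@findings[order(kb@findings$finding_id), , drop = FALSE]
  ds <- kb@diseases[order(kb@diseases$disease_id), , drop = FALSE]
  as_ <- kb@associations[order(kb@associations$disease_id,
                               kb@associations$finding_id), , drop = FALSE]
  cat_ids <- sort(names(kb@categories))
  dcat <- kb@diseaseCategories

  findings <- lapply(seq_len(nrow(fd)), function(i) {
    x <- list(finding_id = fd$finding_id[i], name = fd$name[i],
              kind = fd$kind[i], cost = fd$cost[i],
              is_core = fd$is_core[i])
    if (!is.na(fd$bundle_id[i])) x$bundle_id <- fd$bundle_id[i]
    x
  })
  diseases <- lapply(seq_len(nrow(ds)), function(i) {
    id <- ds$disease_id[i]
    inc <- kb@incidence[kb@incidence$disease_id == id, , drop = FALSE]
    inc <- inc[order(inc$age_lo), , drop = FALSE]
    list(disease_id = id, name = ds$name[i],
         category_ids = sort(dcat$category_id[dcat$disease_id == id]),
         incidence = list(
           age_bins = lapply(seq_len(nrow(inc)),
                             function(j) c(inc$age_lo[j], inc$age_hi[j])),
           incidence_per_bin = inc$weight,
           gender_multiplier = list(male = ds$male_mult[i],
                                    female = ds$female_mult[i])),
         treatability = ds$treatability[i], severity = ds$severity[i],
         heritable = ds$heritable[i], acuity_class = ds$acuity_class[i])
  })
  assocs <- lapply(seq_len(nrow(as_)), function(i) {
    x <- list(disease_id = as_$disease_id[i], finding_id = as_$finding_id[i],
              frequency = as_$frequency[i],
              onset = c(as_$onset_lo[i], as_$onset_hi[i]))
    if (!is.na(as_$disap_lo[i]))
      x$disappearance <- c(as_$disap_lo[i], as_$disap_hi[i])
    x
  })
  doc <- list(findings = findings, diseases = diseases,
              associations = assocs,
              categories = as.list(kb@categories[cat_ids]),
              core_checklist = sort(kb@coreChecklist))
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}

.num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
.chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)

.kbFromList <- function(doc) {
  for (key in c("findings", "diseases", "associations"))
    if (is.null(doc[[key]]))
      stop(sprintf("knowledge base document lacks key '%s'", key),
           call. = FALSE)
  fl <- doc$findings
  findings <- data.frame(
    finding_id = vapply(fl, function(x) .chr(x$finding_id), ""),
    name = vapply(fl, function(x) .chr(x$name), ""),
    kind = vapply(fl, function(x) .chr(x$kind %||% "clinical"), ""),
    cost = vapply(fl, function(x) .num(x$cost %||% 1), 0),
    bundle_id = vapply(fl, function(x) .chr(x$bundle_id), ""),
    is_core = vapply(fl, function(x) isTRUE(x$is_core), NA))

  dl <- doc$diseases
  diseases <- data.frame(
    disease_id = vapply(dl, function(x) .chr(x$disease_id), ""),
    name = vapply(dl, function(x) .chr(x$name), ""),
    treatability = vapply(dl, function(x) .num(x$treatability %||% 0.5), 0),
    severity = vapply(dl, function(x) .num(x$severity %||% 0.5), 0),
    heritable = vapply(dl, function(x) isTRUE(x$heritable), NA),
    acuity_class = vapply(dl,
      function(x) .chr(x$acuity_class %||% "unknown"), ""),
    male_mult = vapply(dl,
      function(x) .num(x$incidence$gender_multiplier$male %||% 1), 0),
    female_mult = vapply(dl,
      function(x) .num(x$incidence$gender_multiplier$female %||% 1), 0))

  inc_rows <- lapply(dl, function(x) {
    bins <- x$incidence$age_bins
    w <- as.numeric(unlist(x$incidence$incidence_per_bin))
    data.frame(disease_id = .chr(x$disease_id),
               age_lo = vapply(bins, function(b) .num(b[[1]]), 0),
               age_hi = vapply(bins, function(b) .num(b[[2]]), 0),
               weight = w)
  })
  incidence <- do.call(rbind, inc_rows)

  cat_rows <- lapply(dl, function(x) {
    ids <- unlist(x$category_ids)
    if (!length(ids))
      return(data.frame(disease_id = character(),
                        category_id = character()))
    data.frame(disease_id = .chr(x$disease_id),
               category_id = as.character(ids))
  })
  diseaseCategories <- do.call(rbind, cat_rows)

  al <- doc$associations
  associations <- data.frame(
    disease_id = vapply(al, function(x) .chr(x$disease_id), ""),
    finding_id = vapply(al, function(x) .chr(x$finding_id), ""),
    frequency = vapply(al, function(x) .num(x$frequency), 0),
    onset_lo = vapply(al, function(x) .num(x$onset[[1]]), 0),
    onset_hi = vapply(al, function(x) .num(x$onset[[2]]), 0),
    disap_lo = vapply(al, function(x)
      if (is.null(x$disappearance)) NA_real_ else .num(x$disappearance[[1]]),
      0),
    disap_hi = vapply(al, function(x)
      if (is.null(x$disappearance)) NA_real_ else .num(x$disappearance[[2]]),
      0))

  categories <- vapply(doc$categories %||% list(), as.character, "")
  new("KnowledgeBase", findings = findings, diseases = diseases,
      incidence = incidence, associations = associations,
      diseaseCategories = diseaseCategories, categories = categories,
      coreChecklist = as.character(unlist(doc$core_checklist %||%
                                            character())))
}

.violation <- function(entity_type, entity_id, rule, message) {
  data.frame(entity_type = entity_type, entity_id = entity_id, rule = rule,
             message = message)
}

#' Validate a knowledge base
#'
#' Audits every curation rule: unique ids, resolved foreign keys, frequency
#' in (0, 1], onset/disappearance interval ordering, incidence bins
#' contiguous over [0, 120) with at least one positive weight, finding costs
#' >= 0.1, and the core checklist being a subset of declared findings.
#' Violations are returned as data, one row each, naming the entity and rule;
#' nothing is thrown.
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @return A data.frame with columns entity_type, entity_id, rule, message;
#'   zero rows iff the KB is valid.
#' @examples
#' nrow(validateKB(toyKB()))  # 0
#' @export
validateKB <- function(kb) {
  v <- list()
  fd <- kb@findings; ds <- kb@diseases; as_ <- kb@associations
  inc <- kb@incidence; dcat <- kb@diseaseCategories

  dup <- unique(fd$finding_id[duplicated(fd$finding_id)])
  for (id in dup)
    v[[length(v) + 1L]] <- .violation("finding", id, "unique_id",
                                      "duplicate finding_id")
  bad <- fd$finding_id[!fd$kind %in% FINDING_KINDS]
  for (id in bad)
    v[[length(v) + 1L]] <- .violation("finding", id, "kind_enum",
                                      "unknown finding kind")
  bad <- fd$finding_id[is.na(fd$cost) | fd$cost < 0.1]
  for (id in bad)
    v[[length(v) + 1L]] <- .violation("finding", id, "cost_min",
                                      "FindingDef.cost must be >= 0.1")

  dup <- unique(ds$disease_id[duplicated(ds$disease_id)])
  for (id in dup)
    v[[length(v) + 1L]] <- .violation("disease", id, "unique_id",
                                      "duplicate disease_id")
  bad <- ds$disease_id[is.na(ds$treatability) | ds$treatability < 0 |
                         ds$treatability > 1]
  for (id in bad)
    v[[length(v) + 1L]] <- .violation("disease", id, "treatability_range",
                                      "treatability must be in [0,1]")
  bad <- ds$disease_id[is.na(ds$severity) | ds$severity < 0 |
                         ds$severity > 1]
  for (id in bad)
    v[[length(v) + 1L]] <- .violation("disease", id, "severity_range",
                                      "severity must be in [0,1]")
  bad <- ds$disease_id[!ds$acuity_class %in% ACUITY_CLASSES]
  for (id in bad)
    v[[length(v) + 1L]] <- .violation("disease", id, "acuity_enum",
                                      "unknown acuity_class")
  bad <- ds$disease_id[is.na(ds$male_mult) | ds$male_mult < 0 |
                         is.na(ds$female_mult) | ds$female_mult < 0]
  for (id in bad)
    v[[length(v) + 1L]] <- .violation("disease", id, "gender_mult",
                                      "gender multipliers must be >= 0")

  ## incidence profiles: contiguous bins from 0 to 120, some positive weight
  for (id in ds$disease_id) {
    b <- inc[inc$disease_id == id, , drop = FALSE]
    if (!nrow(b)) {
      v[[length(v) + 1L]] <- .violation("disease", id, "incidence_missing",
                                        "no incidence bins declared")
      next
    }
    b <- b[order(b$age_lo), , drop = FALSE]
    ok <- b$age_lo[1] == 0 && b$age_hi[nrow(b)] == AGE_MAX &&
      all(b$age_lo < b$age_hi) &&
      (nrow(b) == 1L || all(b$age_hi[-nrow(b)] == b$age_lo[-1]))
    if (!ok)
      v[[length(v) + 1L]] <- .violation(
        "disease", id, "incidence_bins",
        sprintf("age bins must be contiguous and cover [0, %d)", AGE_MAX))
    if (any(is.na(b$weight) | b$weight < 0) || !any(b$weight > 0,
                                                    na.rm = TRUE))
      v[[length(v) + 1L]] <- .violation(
        "disease", id, "incidence_weights",
        "bin weights must be nonnegative with at least one > 0")
  }

  akey <- paste(as_$disease_id, as_$finding_id)
  dup <- unique(akey[duplicated(akey)])
  for (k in dup)
    v[[length(v) + 1L]] <- .violation("association", k, "unique_pair",
                                      "duplicate (disease_id, finding_id)")
  for (i in seq_len(nrow(as_))) {
    k <- akey[i]
    if (!as_$disease_id[i] %in% ds$disease_id)
      v[[length(v) + 1L]] <- .violation("association", k, "foreign_key",
                                        "disease_id not declared")
    if (!as_$finding_id[i] %in% fd$finding_id)
      v[[length(v) + 1L]] <- .violation("association", k, "foreign_key",
                                        "finding_id not declared")
    fq <- as_$frequency[i]
    if (is.na(fq) || fq <= 0 || fq > 1)
      v[[length(v) + 1L]] <- .violation(
        "association", k, "frequency_range",
        "DiseaseFinding.frequency must be in (0, 1]")
    if (is.na(as_$onset_lo[i]) || is.na(as_$onset_hi[i]) ||
        as_$onset_lo[i] > as_$onset_hi[i] || as_$onset_lo[i] < 0)
      v[[length(v) + 1L]] <- .violation("association", k, "onset_interval",
                                        "onset interval reversed or invalid")
    dl <- as_$disap_lo[i]; dh <- as_$disap_hi[i]
    if (is.na(dl) != is.na(dh))
      v[[length(v) + 1L]] <- .violation(
        "association", k, "disappearance_interval",
        "disappearance interval must give both endpoints")
    else if (!is.na(dl) && (dl > dh || dh < as_$onset_lo[i]))
      v[[length(v) + 1L]] <- .violation(
        "association", k, "disappearance_interval",
        "disappearance interval reversed or ends before onset begins")
  }

  for (i in seq_len(nrow(dcat))) {
    if (!dcat$disease_id[i] %in% ds$disease_id)
      v[[length(v) + 1L]] <- .violation("category_membership",
                                        dcat$disease_id[i], "foreign_key",
                                        "disease_id not declared")
    if (length(kb@categories) &&
        !dcat$category_id[i] %in% names(kb@categories))
      v[[length(v) + 1L]] <- .violation("category_membership",
                                        dcat$category_id[i], "foreign_key",
                                        "category_id not declared")
  }

  bad <- setdiff(kb@coreChecklist, fd$finding_id)
  for (id in bad)
    v[[length(v) + 1L]] <- .violation("core_checklist", id, "subset",
                                      "checklist id is not a declared finding")

  if (!length(v))
    return(data.frame(entity_type = character(), entity_id = character(),
                      rule = character(), message = character()))
  do.call(rbind, v)
}

#' Curation completeness report
#'
#' For each disease in scope, counts how many findings of a curation
#' checklist carry an association in the knowledge base. Two counts are
#' reported: \code{n_checklist_annotated}, checklist findings with any
#' association (i.e. reviewed, including explicit near-zero "characteristically
#' absent" codes), and \code{n_checklist_informative}, those with frequency
#' > 0.05. The audit fraction uses the annotated count.
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @param checklist character vector of finding ids (default: the KB's core
#'   checklist). Must be nonempty.
#' @param scope character vector of disease ids to audit (default: all).
#' @return data.frame with columns disease_id, n_checklist_annotated,
#'   n_checklist_informative, fraction — sorted by ascending fraction (least
#'   completely curated diseases first).
#' @examples
#' completenessReport(toyKB())
#' @export
completenessReport <- function(kb, checklist = coreChecklist(kb),
                               scope = diseases(kb)$disease_id) {
  if (!length(checklist)) stop("checklist must be nonempty")
  if (!length(scope))
    return(data.frame(disease_id = character(),
                      n_checklist_annotated = integer(),
                      n_checklist_informative = integer(),
                      fraction = numeric()))
  as_ <- kb@associations[kb@associations$finding_id %in% checklist &
                           kb@associations$disease_id %in% scope, ,
                         drop = FALSE]
  n_ann <- table(factor(as_$disease_id, levels = scope))
  n_inf <- table(factor(as_$disease_id[as_$frequency > 0.05],
                        levels = scope))
  out <- data.frame(disease_id = scope,
                    n_checklist_annotated = as.integer(n_ann),
                    n_checklist_informative = as.integer(n_inf),
                    fraction = as.integer(n_ann) / length(checklist))
  out <- out[order(out$fraction, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A small built-in example knowledge base
#'
#' Three pediatric rheumatology-flavoured diseases (a systemic arthritis, an
#' acute vasculitis, and an infection-triggered arthritis mimic) with a
#' handful of findings, used in examples and tests. Entirely synthetic
#' illustrative content.
#'
#' @return A \code{\link{KnowledgeBase}}.
#' @examples
#' toyKB()
#' @export
toyKB <- function() {
  findings <- data.frame(
    finding_id = c("fever", "rash", "arthritis_knee", "conjunctivitis",
                   "ana_positive", "esr_high", "tick_exposure"),
    name = c("Fever", "Rash", "Knee arthritis", "Conjunctivitis",
             "ANA positive", "Elevated ESR", "Tick exposure"),
    kind = c("clinical", "clinical", "clinical", "clinical", "lab", "lab",
             "clinical"),
    cost = c(0.1, 0.1, 0.5, 0.2, 5, 2, 0.1),
    bundle_id = c(NA, NA, NA, NA, "b_serology", "b_serology", NA),
    is_core = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  diseases <- data.frame(
    disease_id = c("d_sja", "d_vasc", "d_lyme"),
    name = c("Systemic juvenile arthritis", "Acute febrile vasculitis",
             "Tick-borne arthritis"),
    treatability = c(0.8, 0.9, 0.95), severity = c(0.6, 0.8, 0.4),
    heritable = c(FALSE, FALSE, FALSE),
    acuity_class = c("weeks", "days", "weeks"),
    male_mult = c(1, 1.4, 1), female_mult = c(1, 0.6, 1))
  incidence <- data.frame(
    disease_id = rep(c("d_sja", "d_vasc", "d_lyme"), each = 3),
    age_lo = rep(c(0, 5, 18), 3), age_hi = rep(c(5, 18, 120), 3),
    weight = c(2, 3, 0.5,  5, 1, 0.1,  1, 3, 2))
  associations <- data.frame(
    disease_id = c("d_sja", "d_sja", "d_sja", "d_sja",
                   "d_vasc", "d_vasc", "d_vasc",
                   "d_lyme", "d_lyme", "d_lyme"),
    finding_id = c("fever", "rash", "arthritis_knee", "esr_high",
                   "fever", "rash", "conjunctivitis",
                   "arthritis_knee", "tick_exposure", "esr_high"),
    frequency = c(0.95, 0.8, 0.7, 0.9,  1.0, 0.9, 0.85,  0.9, 0.7, 0.6),
    onset_lo = c(0.5, 0.5, 1, 0.5,  0, 0, 0,  2, 2, 2),
    onset_hi = c(16, 16, 16, 16,  5, 5, 5,  18, 18, 18),
    disap_lo = c(NA, NA, NA, NA,  NA, 1, 1,  NA, NA, NA),
    disap_hi = c(NA, NA, NA, NA,  NA, 8, 8,  NA, NA, NA))
  knowledgeBase(
    findings = findings, diseases = diseases, incidence = incidence,
    associations = associations,
    diseaseCategories = data.frame(
      disease_id = c("d_sja", "d_lyme", "d_vasc"),
      category_id = c("arthritis", "arthritis", "vasculitis")),
    categories = c(arthritis = "Arthritis", vasculitis = "Vasculitis"),
    coreChecklist = c("fever", "rash", "arthritis_knee", "conjunctivitis",
                      "esr_high"))
}

#' A small built-in example patient
#'
#' An 8-year-old girl with fever and rash (onset at age 7.9) and no knee
#' arthritis, matching \code{\link{toyKB}}.
#'
#' @return A \code{\link{PatientProfile}}.
#' @export
toyPatient <- function() {
  patientProfile(
    age = 8, gender = "female",
    observations = data.frame(
      finding_id = c("fever", "rash", "arthritis_knee"),
      state = c("present", "present", "absent"),
      onset_age = c(7.9, 7.9, NA)),
    acuity = "weeks")
}
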