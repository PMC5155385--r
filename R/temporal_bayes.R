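## The diagnostic engine: Bayesian pattern matching over diseases with
## age-dependent priors and temporal finding likelihoods.
##
## Each finding in each disease carries a frequency and linear onset /
## disappearance ramps over age intervals; observations can be present
## (optionally with an onset age), or absent (pertinent negatives). Findings
## are conditionally independent given the disease; the per-disease product
## is accumulated in log space and normalized.

## linear CDF ramp across [lo, hi]; a point interval is a step at lo
.ramp <- function(age, lo, hi) {
  ifelse(lo == hi, as.numeric(age >= lo),
         pmin(1, pmax(0, (age - lo) / (hi - lo))))
}

## disappearance ramp; 0 when no disappearance interval curated
.disapRamp <- function(age, dlo, dhi) {
  ifelse(is.na(dlo), 0, .ramp(age, ifelse(is.na(dlo), 0, dlo),
                              ifelse(is.na(dhi), 0, dhi)))
}

#' Age- and gender-dependent prior weight of a disease
#'
#' Looks up the relative incidence weight of the age bin containing
#' \code{age} and scales it by the gender multiplier (the mean of the male
#' and female multipliers when gender is unspecified). Weights are relative:
#' the engine normalizes them across diseases.
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @param disease_id disease identifier.
#' @param age patient age in years, in [0, 120].
#' @param gender "male", "female" or "unspecified".
#' @return A nonnegative scalar weight.
#' @examples
#' priorWeight(toyKB(), "d_vasc", 3, "male")
#' @export
priorWeight <- function(kb, disease_id, age, gender = "unspecified") {
  if (age < 0 || age > AGE_MAX)
    stop(sprintf("age not covered: %g outside [0, %d]", age, AGE_MAX))
  ds <- kb@diseases[kb@diseases$disease_id == disease_id, , drop = FALSE]
  if (!nrow(ds)) stop(sprintf("unknown disease_id '%s'", disease_id))
  b <- kb@incidence[kb@incidence$disease_id == disease_id, , drop = FALSE]
  hit <- b$age_lo <= age & (age < b$age_hi |
                              (age == AGE_MAX & b$age_hi == AGE_MAX))
  if (!any(hit)) stop(sprintf("age not covered: %g", age))
  w <- b$weight[which(hit)[1]]
  mult <- switch(gender,
                 male = ds$male_mult, female = ds$female_mult,
                 unspecified = (ds$male_mult + ds$female_mult) / 2,
                 stop(sprintf("unknown gender '%s'", gender)))
  w * mult
}

## vectorized prior over all diseases in kb
.priorVector <- function(kb, age, gender) {
  inc <- kb@incidence
  hit <- inc$age_lo <= age & (age < inc$age_hi |
                                (age == AGE_MAX & inc$age_hi == AGE_MAX))
  hits <- inc[hit, , drop = FALSE]
  ds <- kb@diseases
  w <- hits$weight[match(ds$disease_id, hits$disease_id)]
  if (anyNA(w)) stop(sprintf("age not covered: %g", age))
  mult <- switch(gender,
                 male = ds$male_mult, female = ds$female_mult,
                 unspecified = (ds$male_mult + ds$female_mult) / 2,
                 stop(sprintf("unknown gender '%s'", gender)))
  w * mult
}

#' Probability a finding is present at a given age
#'
#' For a curated disease-finding association, the probability the finding is
#' expressed and observable at \code{age}: frequency times the onset ramp
#' (linear CDF across the onset interval) times one minus the disappearance
#' ramp (zero if no disappearance interval is curated). Vectorized over
#' association rows.
#'
#' @param assoc one or more rows of the association table (columns frequency,
#'   onset_lo, onset_hi, disap_lo, disap_hi).
#' @param age age in years.
#' @return Numeric vector of probabilities in [0, 1].
#' @examples
#' a <- data.frame(frequency = 0.8, onset_lo = 2, onset_hi = 6,
#'                 disap_lo = NA, disap_hi = NA)
#' probPresentAtAge(a, 4)  # 0.4: halfway up the onset ramp
#' @export
probPresentAtAge <- function(assoc, age) {
  assoc$frequency * .ramp(age, assoc$onset_lo, assoc$onset_hi) *
    (1 - .disapRamp(age, assoc$disap_lo, assoc$disap_hi))
}

#' Onset-ramp probability mass around a reported onset age
#'
#' Mass of the onset-age distribution (uniform over the onset interval; a
#' point mass for a degenerate interval) falling inside the bin
#' \code{[onset_age - bin_width/2, onset_age + bin_width/2]}. Used to score a
#' patient-reported onset age against an association's onset interval.
#' Vectorized over association rows.
#'
#' @param assoc association row(s) with columns onset_lo, onset_hi.
#' @param onset_age reported onset age in years.
#' @param bin_width bin width in years, > 0.
#' @return Numeric vector of masses in [0, 1].
#' @examples
#' a <- data.frame(onset_lo = 0, onset_hi = 10)
#' onsetBinMass(a, 5, 0.5)  # 0.05
#' @export
onsetBinMass <- function(assoc, onset_age, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  a <- onset_age - bin_width / 2
  b <- onset_age + bin_width / 2
  ifelse(assoc$onset_lo == assoc$onset_hi,
         as.numeric(assoc$onset_lo >= a & assoc$onset_lo <= b),
         .ramp(b, assoc$onset_lo, assoc$onset_hi) -
           .ramp(a, assoc$onset_lo, assoc$onset_hi))
}

## Likelihood of one observation under every disease, in kb@diseases order.
## Curated pairs use the temporal model; uncurated pairs fall back to the
## background rate f0 (with a uniform-onset density over [0, age] when an
## onset age was reported). Floored at eps_floor.
.likelihoodVector <- function(kb, obs_finding, obs_state, obs_onset, age,
                              params) {
  ds_ids <- kb@diseases$disease_id
  as_ <- kb@associations
  rows <- as_[as_$finding_id == obs_finding, , drop = FALSE]
  idx <- match(ds_ids, rows$disease_id)
  curated <- !is.na(idx)
  L <- numeric(length(ds_ids))

  if (obs_state == "present" && !is.na(obs_onset)) {
    onset_mult <- if (age <= 0) 1 else min(params@bin_width / age, 1)
    L[!curated] <- params@f0 * onset_mult
    if (any(curated)) {
      r <- rows[idx[curated], , drop = FALSE]
      L[curated] <- r$frequency *
        onsetBinMass(r, obs_onset, params@bin_width) *
        (1 - .disapRamp(age, r$disap_lo, r$disap_hi))
    }
  } else if (obs_state == "present") {
    L[!curated] <- params@f0
    if (any(curated))
      L[curated] <- probPresentAtAge(rows[idx[curated], , drop = FALSE], age)
  } else {
    L[!curated] <- 1 - params@f0
    if (any(curated))
      L[curated] <- 1 - probPresentAtAge(rows[idx[curated], , drop = FALSE],
                                         age)
  }
  pmax(L, params@eps_floor)
}

#' Likelihood of a single observation under a disease
#'
#' The temporal likelihood used by \code{\link{posterior}}: for a present
#' finding without onset age, the probability it is present at the patient's
#' age; with a reported onset age, frequency times the onset-bin mass times
#' the probability it has not yet disappeared; for an absent finding
#' (pertinent negative), the complement of presence. Disease-finding pairs
#' with no curated association use the background rate \code{f0}. The result
#' is floored at \code{eps_floor}.
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @param disease_id disease identifier.
#' @param obs a list or one-row data.frame with fields finding_id, state and
#'   optionally onset_age.
#' @param age patient age in years.
#' @param params an \code{\link{engineParams}} object.
#' @return A positive likelihood.
#' @examples
#' kb <- toyKB()
#' obs <- list(finding_id = "fever", state = "absent", onset_age = NA)
#' observationLikelihood(kb, "d_vasc", obs, 10, engineParams())
#' @export
observationLikelihood <- function(kb, disease_id, obs, age,
                                  params = engineParams()) {
  if (!obs$finding_id %in% kb@findings$finding_id)
    stop(sprintf("unknown finding_id '%s'", obs$finding_id))
  i <- match(disease_id, kb@diseases$disease_id)
  if (is.na(i)) stop(sprintf("unknown disease_id '%s'", disease_id))
  onset <- if (is.null(obs$onset_age)) NA_real_ else obs$onset_age
  .likelihoodVector(kb, obs$finding_id, obs$state, onset, age, params)[i]
}

## acuity likelihood per disease for an observed acuity class
.acuityVector <- function(kb, acuity_obs, params) {
  cls <- kb@diseases$acuity_class
  obs_idx <- match(acuity_obs, ACUITY_CLASSES)
  d_idx <- match(cls, ACUITY_CLASSES)
  gap <- abs(d_idx - obs_idx)
  out <- ifelse(gap == 0, params@acuity_match,
                ifelse(gap == 1, params@acuity_near, params@acuity_far))
  out[cls == "unknown"] <- 1   # no acuity curated: neutral
  out
}

#' Posterior differential diagnosis for a patient
#'
#' Computes the normalized posterior over all diseases in the knowledge base:
#' age/gender incidence prior times the product of observation likelihoods
#' (conditionally independent findings, accumulated in log space). An
#' observed acuity-of-onset class, if present on the profile, acts as one
#' extra categorical observation matched against each disease's acuity class
#' on the log-time scale (exact / adjacent / distant class); diseases with
#' unknown acuity are unaffected by it.
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @param patient a \code{\link{PatientProfile}}.
#' @param params an \code{\link{engineParams}} object.
#' @return A \code{\link{Differential}}: diseases sorted by decreasing
#'   posterior (ties broken lexicographically), posteriors summing to 1.
#' @examples
#' d <- posterior(toyKB(), toyPatient())
#' entries(d)
#' @export
posterior <- function(kb, patient, params = engineParams()) {
  validObject(patient)
  w <- .priorVector(kb, patient@age, patient@gender)
  if (all(w <= 0)) stop("no admissible disease: all priors are zero")
  obs <- patient@observations
  bad <- setdiff(obs$finding_id, kb@findings$finding_id)
  if (length(bad))
    stop(sprintf("unknown finding_id '%s'", bad[1]))

  loglik <- numeric(nrow(kb@diseases))
  for (i in seq_len(nrow(obs)))
    loglik <- loglik + log(.likelihoodVector(
      kb, obs$finding_id[i], obs$state[i], obs$onset_age[i], patient@age,
      params))
  if (!is.na(patient@acuity))
    loglik <- loglik + log(.acuityVector(kb, patient@acuity, params))

  logpost <- ifelse(w > 0, log(w) + loglik, -Inf)
  lse <- .logSumExp(logpost)
  if (!is.finite(lse)) stop("no admissible disease: posterior underflow")
  p <- exp(logpost - lse)
  p <- p / sum(p)

  ids <- kb@diseases$disease_id
  o <- order(-p, ids, method = "radix")
  log_evidence <- .logSumExp(log(w / sum(w)) + loglik)
  new("Differential",
      entries = data.frame(disease_id = ids[o], posterior = p[o],
                           row.names = NULL),
      logEvidence = log_evidence)
}

#' Aggregate a differential into disease categories
#'
#' Sums posterior mass over each category's member diseases; a disease
#' belonging to several categories contributes to each of them (so category
#' masses can exceed 1 in total).
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @param diff a \code{\link{Differential}}.
#' @return data.frame with columns category_id and posterior, sorted by
#'   decreasing posterior (ties broken by category_id).
#' @examples
#' expandCategories(toyKB(), posterior(toyKB(), toyPatient()))
#' @export
expandCategories <- function(kb, diff) {
  e <- diff@entries
  m <- merge(kb@diseaseCategories, e, by = "disease_id")
  if (!nrow(m))
    return(data.frame(category_id = character(), posterior = numeric()))
  agg <- aggregate(posterior ~ category_id, data = m, FUN = sum)
  agg <- agg[order(-agg$posterior, agg$category_id, method = "radix"), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
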