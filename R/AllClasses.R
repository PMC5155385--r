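## Central S4 classes. Structural validity (column presence, types, ranges that
## can never be meaningful) lives here; semantic curation checks that a user
## wants reported as data, not errors, live in validateKB().

#' @import methods
NULL

## controlled vocabularies
FINDING_KINDS  <- c("clinical", "lab", "imaging", "acuity")
ACUITY_CLASSES <- c("minutes", "hours", "days", "weeks", "months", "years",
                    "unknown")
GENDERS        <- c("male", "female", "unspecified")
OBS_STATES     <- c("present", "absent")
AGE_MAX        <- 120

.checkCols <- function(df, what, cols) {
  if (!is.data.frame(df))
    return(sprintf("'%s' must be a data.frame", what))
  missing <- setdiff(cols, names(df))
  if (length(missing))
    return(sprintf("'%s' lacks column(s): %s", what,
                   paste(missing, collapse = ", ")))
  NULL
}

#' Engine tuning parameters
#'
#' Numerical parameters of the diagnostic engine. \code{eps_floor} is the
#' lower floor applied to every observation likelihood (robustness to curation
#' gaps and data-entry errors); \code{f0} is the background rate at which a
#' finding occurs in a disease whose association was never curated;
#' \code{bin_width} (years) discretizes onset ages when a patient reports one;
#' \code{acuity_match}/\code{acuity_near}/\code{acuity_far} are the likelihoods
#' of an observed acuity-of-onset class given an exact, adjacent, or distant
#' disease acuity class.
#'
#' @slot eps_floor numeric likelihood floor, in (0, 1).
#' @slot f0 numeric background finding frequency, in (0, 1).
#' @slot bin_width numeric onset discretization width in years, > 0.
#' @slot acuity_match,acuity_near,acuity_far numeric acuity likelihoods.
#' @exportClass EngineParams
setClass("EngineParams",
  representation(eps_floor = "numeric", f0 = "numeric", bin_width = "numeric",
                 acuity_match = "numeric", acuity_near = "numeric",
                 acuity_far = "numeric"),
  prototype(eps_floor = 1e-4, f0 = 0.005, bin_width = 0.25,
            acuity_match = 1.0, acuity_near = 0.5, acuity_far = 0.1),
  validity = function(object) {
    msg <- character()
    for (s in c("eps_floor", "f0", "bin_width", "acuity_match", "acuity_near",
                "acuity_far")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    if (length(object@eps_floor) == 1L && object@eps_floor >= 1)
      msg <- c(msg, "'eps_floor' must be < 1")
    if (length(object@f0) == 1L && object@f0 >= 1)
      msg <- c(msg, "'f0' must be < 1")
    if (length(msg)) msg else TRUE
  })

#' Construct engine parameters
#'
#' @param eps_floor likelihood floor (default 1e-4).
#' @param f0 background finding frequency for uncurated disease-finding pairs
#'   (default 0.005).
#' @param bin_width onset-age discretization width in years (default 0.25).
#' @param acuity_match,acuity_near,acuity_far acuity class match likelihoods
#'   (defaults 1.0, 0.5, 0.1).
#' @return An \code{EngineParams} object.
#' @examples
#' engineParams(f0 = 0.01)
#' @export
engineParams <- function(eps_floor = 1e-4, f0 = 0.005, bin_width = 0.25,
                         acuity_match = 1.0, acuity_near = 0.5,
                         acuity_far = 0.1) {
  new("EngineParams", eps_floor = eps_floor, f0 = f0, bin_width = bin_width,
      acuity_match = acuity_match, acuity_near = acuity_near,
      acuity_far = acuity_far)
}

#' Disease-finding knowledge base
#'
#' Container for a curated knowledge base: finding definitions, diseases with
#' age/gender incidence profiles, disease-finding associations carrying a
#' frequency and onset/disappearance age intervals, disease category
#' memberships, and the core-checklist finding set used for curation audits.
#'
#' Tables are plain data.frames:
#' \describe{
#'   \item{findings}{finding_id, name, kind (clinical/lab/imaging/acuity),
#'     cost (relative units, >= 0.1), bundle_id (NA if not bundled), is_core.}
#'   \item{diseases}{disease_id, name, treatability, severity (both in [0,1]),
#'     heritable, acuity_class, male_mult, female_mult (gender incidence
#'     multipliers).}
#'   \item{incidence}{disease_id, age_lo, age_hi, weight — contiguous
#'     half-open age bins covering [0, 120) with relative incidence weights.}
#'   \item{associations}{disease_id, finding_id, frequency in (0,1],
#'     onset_lo, onset_hi, disap_lo, disap_hi (disappearance NA if absent).}
#'   \item{diseaseCategories}{disease_id, category_id.}
#' }
#'
#' @slot findings,diseases,incidence,associations,diseaseCategories data.frame.
#' @slot categories named character vector, category_id -> display name.
#' @slot coreChecklist character vector of core finding ids.
#' @seealso \code{\link{loadKB}}, \code{\link{validateKB}},
#'   \code{\link{generateKB}}
#' @exportClass KnowledgeBase
setClass("KnowledgeBase",
  representation(findings = "data.frame", diseases = "data.frame",
                 incidence = "data.frame", associations = "data.frame",
                 diseaseCategories = "data.frame", categories = "character",
                 coreChecklist = "character"),
  validity = function(object) {
    msg <- c(
      .checkCols(object@findings, "findings",
                 c("finding_id", "name", "kind", "cost", "bundle_id",
                   "is_core")),
      .checkCols(object@diseases, "diseases",
                 c("disease_id", "name", "treatability", "severity",
                   "heritable", "acuity_class", "male_mult", "female_mult")),
      .checkCols(object@incidence, "incidence",
                 c("disease_id", "age_lo", "age_hi", "weight")),
      .checkCols(object@associations, "associations",
                 c("disease_id", "finding_id", "frequency", "onset_lo",
                   "onset_hi", "disap_lo", "disap_hi")),
      .checkCols(object@diseaseCategories, "diseaseCategories",
                 c("disease_id", "category_id")))
    if (length(msg)) msg else TRUE
  })

#' Construct a knowledge base
#'
#' Assembles a \code{KnowledgeBase} from its component tables. Missing optional
#' columns are filled with defaults (cost 1, bundle_id NA, is_core FALSE,
#' treatability/severity 0.5, heritable FALSE, acuity_class "unknown", gender
#' multipliers 1). Only structural checks run here; use
#' \code{\link{validateKB}} for the full curation audit.
#'
#' @param findings data.frame with at least finding_id and name.
#' @param diseases data.frame with at least disease_id and name.
#' @param incidence data.frame of age bins (disease_id, age_lo, age_hi, weight).
#' @param associations data.frame of disease-finding associations.
#' @param diseaseCategories data.frame of (disease_id, category_id) pairs.
#' @param categories named character vector mapping category ids to names.
#' @param coreChecklist character vector of core-checklist finding ids.
#' @return A \code{KnowledgeBase}.
#' @export
knowledgeBase <- function(findings, diseases, incidence, associations,
                          diseaseCategories = data.frame(
                            disease_id = character(),
                            category_id = character()),
                          categories = character(),
                          coreChecklist = character()) {
  findings <- .fillDefaults(findings, list(
    cost = 1, bundle_id = NA_character_, is_core = FALSE))
  diseases <- .fillDefaults(diseases, list(
    treatability = 0.5, severity = 0.5, heritable = FALSE,
    acuity_class = "unknown", male_mult = 1, female_mult = 1))
  associations <- .fillDefaults(associations, list(
    disap_lo = NA_real_, disap_hi = NA_real_))
  if (is.null(names(categories)) && length(categories))
    names(categories) <- categories
  new("KnowledgeBase", findings = findings, diseases = diseases,
      incidence = incidence, associations = associations,
      diseaseCategories = diseaseCategories,
      categories = categories, coreChecklist = coreChecklist)
}

.fillDefaults <- function(df, defaults) {
  for (nm in names(defaults))
    if (!nm %in% names(df))
      df[[nm]] <- if (nrow(df)) rep(defaults[[nm]], nrow(df)) else
        defaults[[nm]][0]
  df
}

#' Patient profile
#'
#' A patient's age, gender, observed findings (present/absent, with an
#' optional onset age for present findings) and, optionally, the observed
#' acuity of onset of the illness.
#'
#' @slot age numeric, years in [0, 120].
#' @slot gender "male", "female" or "unspecified".
#' @slot observations data.frame with columns finding_id, state
#'   ("present"/"absent"), onset_age (NA if not reported), value_note
#'   (free text, ignored by the engine).
#' @slot acuity observed acuity class or NA.
#' @exportClass PatientProfile
setClass("PatientProfile",
  representation(age = "numeric", gender = "character",
                 observations = "data.frame", acuity = "character"),
  prototype(acuity = NA_character_),
  validity = function(object) {
    msg <- character()
    if (length(object@age) != 1L || is.na(object@age) ||
        object@age < 0 || object@age > AGE_MAX)
      msg <- c(msg, sprintf("age must be a single value in [0, %d]", AGE_MAX))
    if (length(object@gender) != 1L || !object@gender %in% GENDERS)
      msg <- c(msg, sprintf("gender must be one of: %s",
                            paste(GENDERS, collapse = ", ")))
    m <- .checkCols(object@observations, "observations",
                    c("finding_id", "state", "onset_age", "value_note"))
    if (!is.null(m)) return(c(msg, m))
    obs <- object@observations
    if (anyDuplicated(obs$finding_id))
      msg <- c(msg, "duplicate finding_id among observations")
    if (!all(obs$state %in% OBS_STATES))
      msg <- c(msg, "observation state must be 'present' or 'absent'")
    has_onset <- !is.na(obs$onset_age)
    if (any(has_onset & obs$state == "absent"))
      msg <- c(msg, "onset_age only allowed when state is 'present'")
    if (length(object@age) == 1L && !is.na(object@age) &&
        any(has_onset & (obs$onset_age < 0 | obs$onset_age > object@age)))
      msg <- c(msg, "onset_age must lie in [0, patient age]")
    if (!is.na(object@acuity) && !object@acuity %in% ACUITY_CLASSES)
      msg <- c(msg, "acuity must be a valid acuity class or NA")
    if (length(msg)) msg else TRUE
  })

#' Construct a patient profile
#'
#' @param age patient age in years, in [0, 120].
#' @param gender "male", "female" or "unspecified".
#' @param observations data.frame with columns finding_id and state, and
#'   optionally onset_age and value_note; or NULL for no observations.
#' @param acuity optional observed acuity-of-onset class
#'   ("minutes" ... "years").
#' @return A \code{PatientProfile}.
#' @examples
#' patientProfile(8, "female",
#'   data.frame(finding_id = c("f1", "f2"),
#'              state = c("present", "absent"),
#'              onset_age = c(6.5, NA)))
#' @export
patientProfile <- function(age, gender = "unspecified", observations = NULL,
                           acuity = NA_character_) {
  if (is.null(observations))
    observations <- data.frame(finding_id = character(), state = character(),
                               onset_age = numeric(), value_note = character())
  observations <- .fillDefaults(observations,
                                list(onset_age = NA_real_,
                                     value_note = NA_character_))
  new("PatientProfile", age = as.numeric(age), gender = gender,
      observations = observations, acuity = as.character(acuity))
}

#' Ranked differential diagnosis
#'
#' Ordered posterior distribution over diseases. Entries are sorted by
#' decreasing posterior, ties broken lexicographically by disease_id; the
#' posteriors sum to 1 within 1e-9.
#'
#' @slot entries data.frame with columns disease_id and posterior.
#' @slot logEvidence log of the normalizing constant (model evidence).
#' @exportClass Differential
setClass("Differential",
  representation(entries = "data.frame", logEvidence = "numeric"),
  validity = function(object) {
    m <- .checkCols(object@entries, "entries", c("disease_id", "posterior"))
    if (!is.null(m)) return(m)
    msg <- character()
    p <- object@entries$posterior
    if (nrow(object@entries)) {
      if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, "posteriors must sum to 1 (tolerance 1e-9)")
      o <- order(-p, object@entries$disease_id)
      if (!identical(o, seq_along(p)))
        msg <- c(msg, "entries must be sorted by decreasing posterior, ties lexicographic")
    }
    if (length(msg)) msg else TRUE
  })

#' Noise (user-input-error) configuration
#'
#' Probabilities of the four data-entry error modes applied per observation
#' when corrupting a simulated patient profile: dropping the onset age of a
#' present finding, omitting an observation entirely, misinterpreting it
#' (flipping present/absent), and entering a spurious finding not in the
#' vignette.
#'
#' @slot p_drop_onset,p_omit_finding,p_misinterpret,p_spurious numeric in
#'   [0, 1].
#' @exportClass NoiseConfig
setClass("NoiseConfig",
  representation(p_drop_onset = "numeric", p_omit_finding = "numeric",
                 p_misinterpret = "numeric", p_spurious = "numeric"),
  prototype(p_drop_onset = 0, p_omit_finding = 0, p_misinterpret = 0,
            p_spurious = 0),
  validity = function(object) {
    msg <- character()
    for (s in c("p_drop_onset", "p_omit_finding", "p_misinterpret",
                "p_spurious")) {
      v <- slot(object, s)
      if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
        msg <- c(msg, sprintf("'%s' must be a probability in [0,1]", s))
    }
    if (length(msg)) msg else TRUE
  })

#' @param p_drop_onset,p_omit_finding,p_misinterpret,p_spurious per-observation
#'   probabilities of each input-error mode (all default 0 = noise off).
#' @return A \code{NoiseConfig}.
#' @rdname NoiseConfig-class
#' @export
noiseConfig <- function(p_drop_onset = 0, p_omit_finding = 0,
                        p_misinterpret = 0, p_spurious = 0) {
  new("NoiseConfig", p_drop_onset = p_drop_onset,
      p_omit_finding = p_omit_finding, p_misinterpret = p_misinterpret,
      p_spurious = p_spurious)
}

#' Synthetic knowledge-base / patient simulation configuration
#'
#' Parameters of the synthetic generator. The scale defaults (5405 diseases,
#' a mean of 22 curated findings per disease) emulate the deployed database
#' this package's engine models; the distributional defaults are documented
#' in the methods vignette.
#'
#' @slot seed integer random seed.
#' @slot n_diseases,n_findings integer counts.
#' @slot findings_per_disease_mean mean number of associations per disease.
#' @slot frequency_beta length-2 (alpha, beta) for Beta-sampled frequencies.
#' @slot onset_span_years length-2 range of onset-interval widths (years).
#' @slot p_disappearance probability an association has a disappearance
#'   interval.
#' @slot incidence_lognormal length-2 (mu, sigma) of log-normal incidence
#'   weights.
#' @slot p_core fraction of findings flagged as core-checklist members.
#' @slot noise a \code{NoiseConfig}.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(seed = "numeric", n_diseases = "numeric",
                 n_findings = "numeric", findings_per_disease_mean = "numeric",
                 frequency_beta = "numeric", onset_span_years = "numeric",
                 p_disappearance = "numeric", incidence_lognormal = "numeric",
                 p_core = "numeric", noise = "NoiseConfig"),
  validity = function(object) {
    msg <- character()
    for (s in c("n_diseases", "n_findings", "findings_per_disease_mean"))
      if (slot(object, s) < 1) msg <- c(msg, sprintf("'%s' must be >= 1", s))
    for (s in c("p_disappearance", "p_core")) {
      v <- slot(object, s)
      if (v < 0 || v > 1) msg <- c(msg, sprintf("'%s' must be in [0,1]", s))
    }
    if (length(object@frequency_beta) != 2L ||
        any(object@frequency_beta <= 0))
      msg <- c(msg, "'frequency_beta' must be two positive shape parameters")
    if (length(object@onset_span_years) != 2L ||
        any(object@onset_span_years < 0) ||
        diff(object@onset_span_years) < 0)
      msg <- c(msg, "'onset_span_years' must be an increasing length-2 range")
    if (length(object@incidence_lognormal) != 2L ||
        object@incidence_lognormal[2] < 0)
      msg <- c(msg, "'incidence_lognormal' must be (mu, sigma >= 0)")
    if (object@n_findings < object@findings_per_disease_mean)
      msg <- c(msg,
               "'n_findings' must be >= 'findings_per_disease_mean'")
    if (length(msg)) msg else TRUE
  })

#' @param seed integer seed driving all randomness of the generator.
#' @param n_diseases,n_findings numbers of diseases and findings.
#' @param findings_per_disease_mean mean associations per disease.
#' @param frequency_beta Beta(alpha, beta) shapes for association frequencies.
#' @param onset_span_years range of onset interval widths in years.
#' @param p_disappearance probability of a disappearance interval.
#' @param incidence_lognormal (mu, sigma) of log-normal incidence weights.
#' @param p_core fraction of findings on the core checklist.
#' @param noise a \code{\link{noiseConfig}}.
#' @return A \code{SimConfig}.
#' @rdname SimConfig-class
#' @export
simConfig <- function(seed = 1L, n_diseases = 5405, n_findings = 800,
                      findings_per_disease_mean = 22,
                      frequency_beta = c(2, 2), onset_span_years = c(0.5, 8),
                      p_disappearance = 0.2, incidence_lognormal = c(0, 1),
                      p_core = 0.0575, noise = noiseConfig()) {
  new("SimConfig", seed = as.numeric(seed), n_diseases = n_diseases,
      n_findings = n_findings,
      findings_per_disease_mean = findings_per_disease_mean,
      frequency_beta = frequency_beta, onset_span_years = onset_span_years,
      p_disappearance = p_disappearance,
      incidence_lognormal = incidence_lognormal, p_core = p_core,
      noise = noise)
}

#' Fitted logistic GEE
#'
#' Result of \code{\link{geeLogistic}}: marginal logistic regression for
#' clustered binary outcomes with an exchangeable working correlation,
#' moment estimate of the intra-cluster correlation, robust (sandwich)
#' standard errors and per-coefficient Wald chi-square tests.
#'
#' @slot coefficients named numeric vector of coefficients (logit scale).
#' @slot robust_se,naive_se named numeric standard errors.
#' @slot wald,p_value named numeric Wald chi-square statistics (1 df) and
#'   p-values.
#' @slot alpha working exchangeable correlation estimate.
#' @slot phi dispersion (scale) estimate.
#' @slot converged logical; \code{status} carries detail on failure.
#' @slot n_iter,n_clusters,n_obs integers.
#' @slot status character.
#' @exportClass GEEFit
setClass("GEEFit",
  representation(coefficients = "numeric", robust_se = "numeric",
                 naive_se = "numeric", wald = "numeric", p_value = "numeric",
                 alpha = "numeric", phi = "numeric", converged = "logical",
                 n_iter = "integer", n_clusters = "integer",
                 n_obs = "integer", status = "character"))
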