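## Synthetic knowledge bases and simulated patients. The generator is the
## package's test bed: KBs mirror the scale of the deployed database the
## engine models (thousands of diseases, ~22 curated findings each) and
## patients are drawn from the generative mirror of the engine's own model,
## with optional corruption reproducing the observed user-input error modes.
##
## Every operation draws from one explicitly seeded stream and restores the
## caller's RNG state; identical seeds give byte-identical outputs.

## incidence age grid shared by all synthetic diseases (years)
.INC_BREAKS <- c(0, 1, 2, 5, 10, 15, 20, 30, 40, 50, 65, 80, 100, 120)

#' Generate a synthetic knowledge base
#'
#' Draws a complete random knowledge base: findings (clinical/lab/imaging
#' with kind-dependent costs, a fraction flagged core, lab findings partly
#' grouped into bundles), diseases (each with a characteristic peak age
#' shaping both its incidence profile and its findings' onset intervals,
#' log-normal incidence weights, random treatability/severity, gender skew
#' and acuity class — left "unknown" for 40\% of diseases), categories, and
#' disease-finding associations with Beta-sampled frequencies and
#' onset/disappearance intervals anchored near the disease's peak age.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \code{\link{KnowledgeBase}} that passes \code{\link{validateKB}}
#'   with zero violations. Deterministic given \code{config@seed}.
#' @examples
#' kb <- generateKB(simConfig(seed = 1, n_diseases = 20, n_findings = 60,
#'                            findings_per_disease_mean = 8))
#' kb
#' @export
generateKB <- function(config) {
  validObject(config)
  if (config@n_findings < config@findings_per_disease_mean)
    stop("'n_findings' must be >= 'findings_per_disease_mean'")
  .withSeed(config@seed, .generateKBImpl(config))
}

.generateKBImpl <- function(config) {
  nf <- as.integer(config@n_findings)
  nd <- as.integer(config@n_diseases)

  f_ids <- sprintf("f%05d", seq_len(nf))
  kind <- sample(c("clinical", "lab", "imaging"), nf, replace = TRUE,
                 prob = c(0.6, 0.3, 0.1))
  cost <- numeric(nf)
  cost[kind == "clinical"] <- runif(sum(kind == "clinical"), 0.1, 2)
  cost[kind == "lab"] <- runif(sum(kind == "lab"), 1, 10)
  cost[kind == "imaging"] <- runif(sum(kind == "imaging"), 5, 50)
  is_core <- runif(nf) < config@p_core

  ## group ~40% of lab findings into reporting bundles of 2-4
  bundle_id <- rep(NA_character_, nf)
  labs <- which(kind == "lab")
  n_bundled <- floor(0.4 * length(labs))
  pool <- labs[seq_len(n_bundled)]
  bi <- 0L
  while (length(pool) >= 2L) {
    k <- min(sample(2:4, 1L), length(pool))
    bi <- bi + 1L
    bundle_id[pool[seq_len(k)]] <- sprintf("b%04d", bi)
    pool <- pool[-seq_len(k)]
  }
  findings <- data.frame(
    finding_id = f_ids, name = paste("Finding", f_ids), kind = kind,
    cost = round(cost, 3), bundle_id = bundle_id, is_core = is_core)

  n_cat <- max(1L, ceiling(nd / 10))
  cat_ids <- sprintf("c%04d", seq_len(n_cat))
  categories <- stats::setNames(paste("Category", cat_ids), cat_ids)

  d_ids <- sprintf("d%05d", seq_len(nd))
  peak_age <- runif(nd, 0, 80)
  acuity <- ifelse(runif(nd) < 0.4, "unknown",
                   sample(ACUITY_CLASSES[1:6], nd, replace = TRUE))
  diseases <- data.frame(
    disease_id = d_ids, name = paste("Disease", d_ids),
    treatability = round(runif(nd), 3), severity = round(runif(nd), 3),
    heritable = runif(nd) < 0.2, acuity_class = acuity,
    male_mult = round(exp(rnorm(nd, 0, 0.3)), 3),
    female_mult = round(exp(rnorm(nd, 0, 0.3)), 3))

  ## incidence: log-normal bin weights shaped by a kernel around the peak age
  nb <- length(.INC_BREAKS) - 1L
  mids <- (.INC_BREAKS[-1] + .INC_BREAKS[-(nb + 1L)]) / 2
  w <- matrix(rlnorm(nd * nb, config@incidence_lognormal[1],
                     config@incidence_lognormal[2]), nrow = nd)
  w <- w * exp(-outer(peak_age, mids, `-`)^2 / (2 * 10^2))
  incidence <- data.frame(
    disease_id = rep(d_ids, each = nb),
    age_lo = rep(.INC_BREAKS[-(nb + 1L)], nd),
    age_hi = rep(.INC_BREAKS[-1], nd),
    weight = round(as.numeric(t(w)), 8))

  ## associations: ~Poisson(mean) findings per disease, onsets near peak age
  n_assoc_per <- pmin(nf, pmax(1L, rpois(nd, config@findings_per_disease_mean)))
  d_col <- rep(d_ids, n_assoc_per)
  f_col <- unlist(lapply(seq_len(nd), function(i)
    sort(sample(f_ids, n_assoc_per[i]))))
  n_tot <- length(d_col)
  freq <- pmax(0.02, pmin(1, rbeta(n_tot, config@frequency_beta[1],
                                   config@frequency_beta[2])))
  ## onsets anchored at or below the disease peak age, so that patients
  ## presenting around the peak are typically symptomatic
  pk <- rep(peak_age, n_assoc_per)
  onset_lo <- pmax(0, pk - runif(n_tot, 1, 15))
  span <- runif(n_tot, config@onset_span_years[1], config@onset_span_years[2])
  onset_hi <- pmin(AGE_MAX, onset_lo + span)
  has_dis <- runif(n_tot) < config@p_disappearance
  disap_lo <- ifelse(has_dis, onset_lo + runif(n_tot, 1, 15), NA_real_)
  disap_hi <- ifelse(has_dis, disap_lo + runif(n_tot, 1, 10), NA_real_)
  associations <- data.frame(
    disease_id = d_col, finding_id = f_col, frequency = round(freq, 4),
    onset_lo = round(onset_lo, 3), onset_hi = round(onset_hi, 3),
    disap_lo = round(disap_lo, 3), disap_hi = round(disap_hi, 3))

  memberships <- data.frame(
    disease_id = rep(d_ids, times = pmin(n_cat, pmin(3L, 1L + rpois(nd, 0.8)))))
  memberships$category_id <- unlist(lapply(
    table(factor(memberships$disease_id, levels = d_ids)),
    function(k) sort(sample(cat_ids, k))))
  rownames(memberships) <- NULL

  knowledgeBase(findings = findings, diseases = diseases,
                incidence = incidence, associations = associations,
                diseaseCategories = memberships, categories = categories,
                coreChecklist = f_ids[is_core])
}

#' Simulate a patient from a disease
#'
#' The generative mirror of the engine's model: the patient's age is drawn
#' from the disease's incidence profile (gender from its multipliers); each
#' curated finding turns present with its frequency, provided its sampled
#' onset age (uniform over the onset interval) is at or before the patient's
#' age and the sampled disappearance age (if any) is after it; sampled onset
#' ages are recorded on the profile. A Poisson(2)-sized sample of
#' curated-but-absent findings is recorded as pertinent negatives. The
#' disease's acuity class, if curated, becomes the observed acuity.
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @param disease_id the true disease to simulate from.
#' @param config a \code{\link{simConfig}} (only the seed is used here).
#' @param seed RNG seed (defaults to \code{config@seed}).
#' @return list with elements \code{profile} (a
#'   \code{\link{PatientProfile}}) and \code{truth} (the disease id).
#' @examples
#' kb <- generateKB(simConfig(seed = 1, n_diseases = 20, n_findings = 60,
#'                            findings_per_disease_mean = 8))
#' simulatePatient(kb, diseases(kb)$disease_id[1], simConfig(seed = 7))
#' @export
simulatePatient <- function(kb, disease_id, config = simConfig(),
                            seed = config@seed) {
  if (!disease_id %in% kb@diseases$disease_id)
    stop(sprintf("unknown disease_id '%s'", disease_id))
  as_ <- kb@associations[kb@associations$disease_id == disease_id, ,
                         drop = FALSE]
  if (!nrow(as_))
    stop(sprintf("disease '%s' has no curated findings", disease_id))
  .withSeed(seed, {
    b <- kb@incidence[kb@incidence$disease_id == disease_id, , drop = FALSE]
    b <- b[order(b$age_lo), , drop = FALSE]
    mass <- b$weight * (b$age_hi - b$age_lo)
    d <- kb@diseases[kb@diseases$disease_id == disease_id, ]
    as_ <- as_[order(as_$finding_id), , drop = FALSE]
    n <- nrow(as_)

    ## rejection-sample until the patient is symptomatic: a case vignette
    ## describes a patient who presented because findings were observable
    for (attempt in 1:100) {
      bin <- sample.int(nrow(b), 1L, prob = mass)
      age <- runif(1, b$age_lo[bin], b$age_hi[bin])
      gender <- sample(c("male", "female"), 1L,
                       prob = c(d$male_mult, d$female_mult))
      expressed <- runif(n) < as_$frequency
      onset <- runif(n, as_$onset_lo, as_$onset_hi)
      disap <- ifelse(is.na(as_$disap_lo), Inf,
                      runif(n, ifelse(is.na(as_$disap_lo), 0, as_$disap_lo),
                            ifelse(is.na(as_$disap_hi), 1, as_$disap_hi)))
      present <- expressed & onset <= age & age < disap
      if (any(present)) break
    }

    neg_pool <- as_$finding_id[!present]
    n_neg <- min(rpois(1, 2), length(neg_pool))
    negs <- if (n_neg) sort(sample(neg_pool, n_neg)) else character()

    obs <- rbind(
      data.frame(finding_id = as_$finding_id[present],
                 state = rep("present", sum(present)),
                 onset_age = round(onset[present], 4)),
      data.frame(finding_id = negs,
                 state = rep("absent", length(negs)),
                 onset_age = rep(NA_real_, length(negs))))
    acuity <- if (d$acuity_class == "unknown") NA_character_ else
      d$acuity_class
    list(profile = patientProfile(age = age, gender = gender,
                                  observations = obs, acuity = acuity),
         truth = disease_id)
  })
}

#' Corrupt a patient profile with user-input-error noise
#'
#' Applies the four data-entry error modes observed in practice,
#' independently per observation: the onset age of a present finding is
#' dropped with \code{p_drop_onset}; an observation is omitted entirely with
#' \code{p_omit_finding}; its present/absent state is flipped
#' (misinterpreted) with \code{p_misinterpret}; and for each original
#' observation a spurious finding not in the vignette is entered with
#' \code{p_spurious}.
#'
#' @param profile a \code{\link{PatientProfile}}.
#' @param noise a \code{\link{noiseConfig}}.
#' @param kb the \code{\link{KnowledgeBase}} (source of spurious findings).
#' @param seed RNG seed.
#' @return A corrupted \code{\link{PatientProfile}}; deterministic given
#'   \code{seed}.
#' @export
corruptProfile <- function(profile, noise, kb, seed = 1L) {
  validObject(noise)
  .withSeed(seed, {
    obs <- profile@observations
    n <- nrow(obs)

    flip <- runif(n) < noise@p_misinterpret
    new_state <- ifelse(flip,
                        ifelse(obs$state == "present", "absent", "present"),
                        obs$state)
    obs$onset_age[flip] <- NA_real_   # flipped observations lose the onset
    obs$state <- new_state

    drop <- runif(n) < noise@p_drop_onset
    obs$onset_age[drop] <- NA_real_

    keep <- runif(n) >= noise@p_omit_finding
    obs <- obs[keep, , drop = FALSE]

    n_spur <- rbinom(1, n, noise@p_spurious)
    pool <- setdiff(kb@findings$finding_id, obs$finding_id)
    n_spur <- min(n_spur, length(pool))
    if (n_spur > 0) {
      spur <- sort(sample(pool, n_spur))
      obs <- rbind(obs[, c("finding_id", "state", "onset_age")],
                   data.frame(finding_id = spur, state = "present",
                              onset_age = NA_real_))
    }
    patientProfile(age = profile@age, gender = profile@gender,
                   observations = obs[, c("finding_id", "state",
                                          "onset_age")],
                   acuity = profile@acuity)
  })
}
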