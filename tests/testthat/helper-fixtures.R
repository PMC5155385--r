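# Shared test fixtures, built in code.

# A deterministic KB whose parameters are all dyadic rationals (exactly
# representable doubles), so direct-product oracle arithmetic carries no
# representation error.
dyadicKB <- function(n_diseases = 10, n_findings = 12, seed = 42) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    f_ids <- sprintf("f%02d", seq_len(n_findings))
    d_ids <- sprintf("d%02d", seq_len(n_diseases))
    findings <- data.frame(
      finding_id = f_ids, name = f_ids,
      kind = sample(c("clinical", "lab"), n_findings, replace = TRUE),
      cost = sample(c(0.5, 1, 2, 4), n_findings, replace = TRUE),
      bundle_id = NA_character_, is_core = FALSE)
    diseases <- data.frame(
      disease_id = d_ids, name = d_ids,
      treatability = sample(c(0.25, 0.5, 0.75), n_diseases, replace = TRUE),
      severity = sample(c(0.25, 0.5, 0.75), n_diseases, replace = TRUE),
      heritable = FALSE,
      acuity_class = sample(c("days", "weeks", "years", "unknown"),
                            n_diseases, replace = TRUE),
      male_mult = sample(c(0.5, 1, 2), n_diseases, replace = TRUE),
      female_mult = sample(c(0.5, 1, 2), n_diseases, replace = TRUE))
    incidence <- do.call(rbind, lapply(d_ids, function(d) data.frame(
      disease_id = d, age_lo = c(0, 16, 64), age_hi = c(16, 64, 120),
      weight = sample(c(1, 2, 4), 3, replace = TRUE))))
    assoc <- do.call(rbind, lapply(d_ids, function(d) {
      k <- sample(4:8, 1)
      fs <- sort(sample(f_ids, k))
      lo <- sample(c(0, 2, 4, 8), k, replace = TRUE)
      hi <- lo + sample(c(0, 2, 4, 8), k, replace = TRUE)
      has_dis <- runif(k) < 0.3
      dlo <- ifelse(has_dis, hi + sample(c(2, 4), k, replace = TRUE),
                    NA_real_)
      data.frame(disease_id = d, finding_id = fs,
                 frequency = sample(c(0.25, 0.5, 0.75, 1), k,
                                    replace = TRUE),
                 onset_lo = lo, onset_hi = hi,
                 disap_lo = dlo, disap_hi = dlo + 8)
    }))
    knowledgeBase(
      findings = findings, diseases = diseases, incidence = incidence,
      associations = assoc,
      diseaseCategories = data.frame(
        disease_id = d_ids,
        category_id = sample(c("catA", "catB", "catC"), n_diseases,
                             replace = TRUE)),
      categories = c(catA = "A", catB = "B", catC = "C"),
      coreChecklist = f_ids[1:4])
  })
}

# a random patient consistent with a KB (findings drawn from the KB,
# dyadic onset ages), for property tests
randomPatient <- function(kb, n_obs = 5, age = NULL, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(age)) age <- sample(c(2, 8, 12.5, 30, 70), 1)
  fs <- sample(findings(kb)$finding_id, n_obs)
  state <- sample(c("present", "absent"), n_obs, replace = TRUE)
  onset <- ifelse(state == "present" & runif(n_obs) < 0.5,
                  round(runif(n_obs, 0, age) * 4) / 4, NA_real_)
  patientProfile(age = age,
                 gender = sample(c("male", "female", "unspecified"), 1),
                 observations = data.frame(finding_id = fs, state = state,
                                           onset_age = onset))
}
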