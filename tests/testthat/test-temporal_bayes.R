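params <- engineParams()

test_that("prior weight is the age-bin incidence times the gender multiplier", {
  kb <- toyKB()
  # uniform single-bin profile: weight constant across ages
  kb1 <- kb
  kb1@incidence <- data.frame(disease_id = diseases(kb)$disease_id,
                              age_lo = 0, age_hi = 120, weight = 1)
  kb1@diseases$male_mult <- 1
  kb1@diseases$female_mult <- 1
  for (a in c(0, 3.7, 119, 120))
    expect_equal(priorWeight(kb1, "d_sja", a, "male"), 1.0)

  # proportionality: d_sja weight 3 vs d_vasc weight 1 in the 5-18 bin
  w1 <- priorWeight(kb, "d_sja", 8, "unspecified")
  w2 <- priorWeight(kb, "d_vasc", 8, "unspecified")
  expect_equal(w1 / w2, 3 / 1)

  expect_error(priorWeight(kb, "d_sja", 121, "male"), "not covered")
  expect_error(priorWeight(kb, "nope", 5, "male"), "unknown disease")
})

test_that("prior weight equals a linear-scan oracle on random profiles", {
  kb <- generateKB(simConfig(seed = 12, n_diseases = 20, n_findings = 80))
  set.seed(99)
  ids <- sample(diseases(kb)$disease_id, 200, replace = TRUE)
  ages <- runif(200, 0, 120)
  genders <- sample(c("male", "female", "unspecified"), 200, replace = TRUE)
  for (i in seq_len(200))
    expect_equal(priorWeight(kb, ids[i], ages[i], genders[i]),
                 oracle_prior(kb, ids[i], ages[i], genders[i]))
})

test_that("presence probability follows the onset/disappearance ramps", {
  a <- data.frame(frequency = 0.8, onset_lo = 2, onset_hi = 6,
                  disap_lo = NA_real_, disap_hi = NA_real_)
  expect_equal(probPresentAtAge(a, 6), 0.8)     # ramp completed
  expect_equal(probPresentAtAge(a, 4), 0.4)     # midpoint of onset ramp
  expect_equal(probPresentAtAge(a, 1), 0)

  b <- data.frame(frequency = 1.0, onset_lo = 0, onset_hi = 0,
                  disap_lo = 10, disap_hi = 20)
  expect_equal(probPresentAtAge(b, 15), 0.5)    # midpoint of disappearance
  expect_equal(probPresentAtAge(b, 25), 0)
})

test_that("onset bin mass matches quadrature over the ramp density", {
  a <- data.frame(onset_lo = 0, onset_hi = 10)
  expect_equal(onsetBinMass(a, 5, 0.5), 0.05)
  pt <- data.frame(onset_lo = 4, onset_hi = 4)
  expect_equal(onsetBinMass(pt, 4, 0.25), 1.0)
  expect_equal(onsetBinMass(pt, 4, 7), 1.0)
  expect_equal(onsetBinMass(pt, 10, 0.25), 0.0)

  set.seed(7)
  for (i in 1:25) {
    lo <- runif(1, 0, 50)
    hi <- lo + runif(1, 0.5, 20)
    o <- runif(1, lo - 2, hi + 2)
    w <- runif(1, 0.1, 3)
    a <- o - w / 2; b <- o + w / 2
    cuts <- sort(unique(c(a, b, pmin(pmax(c(lo, hi), a), b))))
    numeric_mass <- sum(vapply(seq_len(length(cuts) - 1), function(j)
      stats::integrate(function(x) stats::dunif(x, lo, hi), cuts[j],
                       cuts[j + 1])$value, 0))
    got <- onsetBinMass(data.frame(onset_lo = lo, onset_hi = hi), o, w)
    expect_equal(got, numeric_mass, tolerance = 1e-6)
  }
})

test_that("observation likelihood agrees with an independent transcription
           of the branch formulas", {
  # absent certain finding floors at eps
  kb <- toyKB()
  kb@associations[1, c("onset_lo", "onset_hi")] <- 0
  kb@associations$frequency[1] <- 1.0
  L <- observationLikelihood(kb, "d_sja",
                             list(finding_id = "fever", state = "absent"),
                             age = 10, params)
  expect_equal(L, params@eps_floor)

  # absent with prob_present 0.4 -> 0.6
  kb2 <- toyKB()
  kb2@associations$frequency[1] <- 0.4
  kb2@associations[1, c("onset_lo", "onset_hi")] <- 0
  L <- observationLikelihood(kb2, "d_sja",
                             list(finding_id = "fever", state = "absent"),
                             age = 10, params)
  expect_equal(L, 0.6)

  expect_error(observationLikelihood(kb2, "d_sja",
                                     list(finding_id = "zzz",
                                          state = "present"), 5, params),
               "unknown finding")

  # randomized dual-implementation check over all branches
  kbr <- dyadicKB(n_diseases = 8, seed = 31)
  set.seed(8)
  for (i in 1:60) {
    d <- sample(diseases(kbr)$disease_id, 1)
    f <- sample(findings(kbr)$finding_id, 1)
    st <- sample(c("present", "absent"), 1)
    age <- runif(1, 0, 90)
    onset <- if (st == "present" && runif(1) < 0.5) runif(1, 0, age)
    else NA_real_
    got <- observationLikelihood(
      kbr, d, list(finding_id = f, state = st, onset_age = onset), age,
      params)
    expect_equal(got, oracle_likelihood(kbr, d, f, st, onset, age, params))
  }
})

test_that("two-disease posteriors follow the closed-form normalization", {
  # one disease certain for the finding, the other uncurated
  findings <- data.frame(finding_id = "f1", name = "f1", kind = "clinical",
                         cost = 1, bundle_id = NA_character_,
                         is_core = FALSE)
  diseases <- data.frame(
    disease_id = c("dA", "dB"), name = c("A", "B"),
    treatability = 0.5, severity = 0.5, heritable = FALSE,
    acuity_class = "unknown", male_mult = 1, female_mult = 1)
  incidence <- data.frame(disease_id = rep(c("dA", "dB"), each = 1),
                          age_lo = 0, age_hi = 120, weight = 1)
  assoc <- data.frame(disease_id = "dA", finding_id = "f1", frequency = 1.0,
                      onset_lo = 0, onset_hi = 0, disap_lo = NA_real_,
                      disap_hi = NA_real_)
  kb <- knowledgeBase(findings, diseases, incidence, assoc)
  pat <- patientProfile(10, "male",
                        data.frame(finding_id = "f1", state = "present"))
  e <- entries(posterior(kb, pat, params))
  expect_equal(e$posterior[e$disease_id == "dA"], 1 / 1.005,
               tolerance = 1e-12)

  # no observations: posterior recovers the normalized prior
  pat0 <- patientProfile(10, "male")
  e0 <- entries(posterior(kb, pat0, params))
  expect_equal(e0$posterior, c(0.5, 0.5))
})

test_that("posterior matches the direct-product oracle to 1e-9", {
  kb <- dyadicKB(n_diseases = 10, seed = 42)
  for (s in 1:10) {
    pat <- randomPatient(kb, n_obs = 5, seed = s)
    e <- entries(posterior(kb, pat, params))
    expected <- oracle_posterior(kb, pat, params)
    got <- e$posterior[match(names(expected), e$disease_id)]
    expect_lt(max(abs(got - expected)), 1e-9)
    expect_lt(abs(sum(e$posterior) - 1), 1e-9)
  }
})

test_that("acuity observations shift mass toward matching acuity classes", {
  kb <- dyadicKB(n_diseases = 10, seed = 42)
  cls <- diseases(kb)$acuity_class
  pat <- randomPatient(kb, n_obs = 3, seed = 5)
  pat_ac <- patientProfile(pat@age, pat@gender, observations(pat),
                           acuity = "days")
  e0 <- entries(posterior(kb, pat, params))
  e1 <- entries(posterior(kb, pat_ac, params))
  expected <- oracle_posterior(kb, pat_ac, params)
  got <- e1$posterior[match(names(expected), e1$disease_id)]
  expect_lt(max(abs(got - expected)), 1e-9)

  # a "days" disease gains odds over a "years" disease
  d_match <- diseases(kb)$disease_id[cls == "days"][1]
  d_far <- diseases(kb)$disease_id[cls == "years"][1]
  odds0 <- e0$posterior[e0$disease_id == d_match] /
    e0$posterior[e0$disease_id == d_far]
  odds1 <- e1$posterior[e1$disease_id == d_match] /
    e1$posterior[e1$disease_id == d_far]
  expect_gt(odds1, odds0)
})

test_that("posterior is invariant under observation order", {
  kb <- dyadicKB(n_diseases = 10, seed = 42)
  pat <- randomPatient(kb, n_obs = 6, seed = 11)
  obs <- observations(pat)
  pat_rev <- patientProfile(pat@age, pat@gender,
                            obs[rev(seq_len(nrow(obs))), ], pat@acuity)
  expect_equal(entries(posterior(kb, pat, params)),
               entries(posterior(kb, pat_rev, params)))
})

test_that("a pertinent negative lowers the odds of diseases in which the
           finding is common", {
  kb <- dyadicKB(n_diseases = 10, seed = 42)
  as_ <- associations(kb)
  set.seed(21)
  checked <- 0
  for (i in 1:40) {
    pat <- randomPatient(kb, n_obs = 3, seed = 100 + i)
    f <- sample(setdiff(findings(kb)$finding_id,
                        observations(pat)$finding_id), 1)
    pp <- vapply(diseases(kb)$disease_id, function(d)
      oracle_likelihood(kb, d, f, "present", NA_real_, pat@age, params), 0)
    hi <- names(pp)[which.max(pp)]
    lo <- names(pp)[which.min(pp)]
    if (pp[hi] <= pp[lo] + 0.05) next
    e0 <- entries(posterior(kb, pat, params))
    obs2 <- rbind(observations(pat)[, c("finding_id", "state", "onset_age")],
                  data.frame(finding_id = f, state = "absent",
                             onset_age = NA_real_))
    e1 <- entries(posterior(kb, patientProfile(pat@age, pat@gender, obs2),
                            params))
    odds <- function(e, a, b)
      e$posterior[e$disease_id == a] / e$posterior[e$disease_id == b]
    expect_lt(odds(e1, hi, lo), odds(e0, hi, lo))
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("a matching onset age raises the odds against diseases whose
           onset window excludes it", {
  # dIn: onset window contains age 5; dOut: window [20, 30]
  findings <- data.frame(finding_id = "f1", name = "f1", kind = "clinical",
                         cost = 1, bundle_id = NA_character_,
                         is_core = FALSE)
  diseases <- data.frame(
    disease_id = c("dIn", "dOut"), name = c("in", "out"),
    treatability = 0.5, severity = 0.5, heritable = FALSE,
    acuity_class = "unknown", male_mult = 1, female_mult = 1)
  incidence <- data.frame(disease_id = rep(c("dIn", "dOut"), each = 1),
                          age_lo = 0, age_hi = 120, weight = 1)
  assoc <- data.frame(disease_id = c("dIn", "dOut"), finding_id = "f1",
                      frequency = 0.8, onset_lo = c(2, 20),
                      onset_hi = c(8, 30), disap_lo = NA_real_,
                      disap_hi = NA_real_)
  kb <- knowledgeBase(findings, diseases, incidence, assoc)
  mk <- function(onset) patientProfile(
    25, "male", data.frame(finding_id = "f1", state = "present",
                           onset_age = onset))
  odds <- function(e) e$posterior[e$disease_id == "dIn"] /
    e$posterior[e$disease_id == "dOut"]
  no_onset <- odds(entries(posterior(kb, mk(NA_real_), params)))
  with_onset <- odds(entries(posterior(kb, mk(5), params)))
  expect_gte(with_onset, no_onset)
  expect_gt(with_onset, 1)
})

test_that("category expansion equals a brute-force group-by", {
  kb <- dyadicKB(n_diseases = 10, seed = 42)
  d <- posterior(kb, randomPatient(kb, n_obs = 4, seed = 3), params)
  got <- expandCategories(kb, d)
  e <- entries(d)
  dcat <- kb@diseaseCategories
  for (i in seq_len(nrow(got))) {
    members <- dcat$disease_id[dcat$category_id == got$category_id[i]]
    expect_equal(got$posterior[i],
                 sum(e$posterior[e$disease_id %in% members]))
  }
  expect_false(is.unsorted(rev(got$posterior)))

  # all mass on one disease: its categories carry the full mass
  top <- e$disease_id[1]
  single <- new("Differential",
                entries = data.frame(disease_id = top, posterior = 1),
                logEvidence = 0)
  gc1 <- expandCategories(kb, single)
  expect_true(all(gc1$posterior == 1))
  expect_setequal(gc1$category_id, dcat$category_id[dcat$disease_id == top])
})
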