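params <- engineParams()

test_that("predictive presence is the posterior-weighted mixture", {
  # all mass on one disease with prob_present 0.7
  findings <- data.frame(finding_id = c("f1", "f2"), name = c("f1", "f2"),
                         kind = "clinical", cost = 1,
                         bundle_id = NA_character_, is_core = FALSE)
  diseases <- data.frame(
    disease_id = c("dA", "dB"), name = c("A", "B"), treatability = 0.5,
    severity = 0.5, heritable = FALSE, acuity_class = "unknown",
    male_mult = 1, female_mult = 1)
  incidence <- data.frame(disease_id = c("dA", "dB"), age_lo = 0,
                          age_hi = 120, weight = 1)
  assoc <- data.frame(disease_id = c("dA", "dA"),
                      finding_id = c("f1", "f2"),
                      frequency = c(1.0, 0.7), onset_lo = 0, onset_hi = 0,
                      disap_lo = NA_real_, disap_hi = NA_real_)
  kb <- knowledgeBase(findings, diseases, incidence, assoc)

  all_on_A <- new("Differential",
                  entries = data.frame(disease_id = c("dA", "dB"),
                                       posterior = c(1, 0)),
                  logEvidence = 0)
  expect_equal(predictivePresence(kb, all_on_A, "f2", 10, params), 0.7)

  fifty <- new("Differential",
               entries = data.frame(disease_id = c("dA", "dB"),
                                    posterior = c(0.5, 0.5)),
               logEvidence = 0)
  # dA certain, dB uncurated (f0): 0.5*1 + 0.5*0.005
  expect_equal(predictivePresence(kb, fifty, "f1", 10, params), 0.5025)

  expect_error(predictivePresence(kb, fifty, "f1", 10, params,
                                  observed = "f1"), "already observed")

  # random mixture equals brute-force weighted sum
  kbr <- dyadicKB(n_diseases = 10, seed = 42)
  pat <- randomPatient(kbr, n_obs = 3, seed = 2)
  d <- posterior(kbr, pat, params)
  e <- entries(d)
  for (f in setdiff(findings(kbr)$finding_id,
                    observations(pat)$finding_id)[1:5]) {
    expected <- sum(vapply(seq_len(nrow(e)), function(i) {
      pp <- oracle_likelihood(kbr, e$disease_id[i], f, "present", NA_real_,
                              pat@age, engineParams(eps_floor = 1e-300))
      e$posterior[i] * pp
    }, 0))
    expect_equal(predictivePresence(kbr, d, f, pat@age, params), expected,
                 tolerance = 1e-12)
  }
})

test_that("expected entropy reduction behaves like information", {
  findings <- data.frame(finding_id = c("f0", "fd", "fs"),
                         name = c("f0", "fd", "fs"), kind = "clinical",
                         cost = 1, bundle_id = NA_character_,
                         is_core = FALSE)
  diseases <- data.frame(
    disease_id = c("dA", "dB"), name = c("A", "B"), treatability = 0.5,
    severity = 0.5, heritable = FALSE, acuity_class = "unknown",
    male_mult = 1, female_mult = 1)
  incidence <- data.frame(disease_id = c("dA", "dB"), age_lo = 0,
                          age_hi = 120, weight = 1)
  # fd: certain in dA, uncurated in dB (discriminating)
  # fs: frequency 0.5 completed in both (non-discriminating)
  assoc <- data.frame(disease_id = c("dA", "dA", "dB"),
                      finding_id = c("fd", "fs", "fs"),
                      frequency = c(1.0, 0.5, 0.5), onset_lo = 0,
                      onset_hi = 0, disap_lo = NA_real_,
                      disap_hi = NA_real_)
  kb <- knowledgeBase(findings, diseases, incidence, assoc)
  pat <- patientProfile(10, "male")   # uniform posterior over dA, dB

  # near-perfect binary split of two equiprobable diseases: ~1 bit
  gain_d <- expectedEntropyReduction(kb, pat, "fd", params)
  expect_gt(gain_d, 0.9)
  expect_lte(gain_d, 1)

  # identical likelihood in every disease: zero information
  expect_identical(expectedEntropyReduction(kb, pat, "fs", params), 0)

  expect_error(
    expectedEntropyReduction(
      kb, patientProfile(10, "male",
                         data.frame(finding_id = "fd", state = "present")),
      "fd", params),
    "already observed")
})

test_that("entropy reduction matches exhaustive two-branch recomputation
           and is never negative", {
  kb <- dyadicKB(n_diseases = 10, seed = 42)
  set.seed(14)
  for (i in 1:15) {
    pat <- randomPatient(kb, n_obs = 4, seed = 200 + i)
    f <- sample(setdiff(findings(kb)$finding_id,
                        observations(pat)$finding_id), 1)
    got <- expectedEntropyReduction(kb, pat, f, params)
    expect_gte(got, 0)

    # independent recomputation from the oracle posterior
    post <- oracle_posterior(kb, pat, params)
    pd <- vapply(names(post), function(d) {
      pp <- oracle_prob_present_or_f0(kb, d, f, pat@age, params)
      min(max(pp, params@eps_floor), 1 - params@eps_floor)
    }, 0)
    H <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log2(p)) }
    p_plus <- sum(post * pd)
    expected <- H(post) - (p_plus * H(post * pd) +
                             (1 - p_plus) * H(post * (1 - pd)))
    expected <- max(expected, 0)
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("suggestions are ranked by cost-adjusted urgency-weighted gain", {
  kb <- dyadicKB(n_diseases = 10, seed = 42)
  pat <- randomPatient(kb, n_obs = 3, seed = 6)
  sug <- rankSuggestions(kb, pat, params, top_n = 100)
  expect_true(all(sug$expected_gain >= 0))
  expect_true(all(diff(sug$usefulness) <= 0))
  expect_equal(sug$usefulness,
               sug$expected_gain * sug$urgency_weight / sug$cost)

  # a single decisively discriminating finding ranks first
  findings <- data.frame(finding_id = c("fd", "fx"), name = c("fd", "fx"),
                         kind = "clinical", cost = 1,
                         bundle_id = NA_character_, is_core = FALSE)
  diseases <- data.frame(
    disease_id = c("dA", "dB"), name = c("A", "B"), treatability = 0.5,
    severity = 0.5, heritable = FALSE, acuity_class = "unknown",
    male_mult = 1, female_mult = 1)
  incidence <- data.frame(disease_id = c("dA", "dB"), age_lo = 0,
                          age_hi = 120, weight = 1)
  assoc <- data.frame(disease_id = c("dA", "dA", "dB"),
                      finding_id = c("fd", "fx", "fx"),
                      frequency = c(1.0, 0.5, 0.5), onset_lo = 0,
                      onset_hi = 0, disap_lo = NA_real_, disap_hi = NA_real_)
  kb2 <- knowledgeBase(findings, diseases, incidence, assoc)
  s2 <- rankSuggestions(kb2, patientProfile(10, "male"), params)
  expect_equal(s2$target_id[1], "fd")

  # equal gain, costs 1 vs 2: the cheaper test ranks first
  kb3 <- kb2
  kb3@findings <- rbind(kb3@findings,
                        data.frame(finding_id = "fd2", name = "fd2",
                                   kind = "lab", cost = 2,
                                   bundle_id = NA_character_,
                                   is_core = FALSE))
  kb3@associations <- rbind(kb3@associations,
                            data.frame(disease_id = "dA",
                                       finding_id = "fd2", frequency = 1.0,
                                       onset_lo = 0, onset_hi = 0,
                                       disap_lo = NA_real_,
                                       disap_hi = NA_real_))
  s3 <- rankSuggestions(kb3, patientProfile(10, "male"), params)
  expect_equal(s3$target_id[1], "fd")
  gains <- s3$expected_gain[match(c("fd", "fd2"), s3$target_id)]
  expect_equal(gains[1], gains[2])
  expect_lt(match("fd2", s3$target_id), match("fx", s3$target_id))
})

test_that("bundle gain equals exhaustive outcome-tree enumeration", {
  kb <- dyadicKB(n_diseases = 8, seed = 17)
  # make a 3-finding bundle out of the first three findings
  kb@findings$bundle_id[1:3] <- "bx"
  pat <- patientProfile(8, "female")   # prior-only differential
  sug <- rankSuggestions(kb, pat, params, top_n = 100)
  got <- sug[sug$target_id == "bx", ]
  expect_equal(nrow(got), 1L)

  # enumeration over the 8 outcomes from the oracle side
  post <- oracle_posterior(kb, pat, params)
  members <- kb@findings$finding_id[1:3]
  pm <- vapply(members, function(f) vapply(names(post), function(d) {
    pp <- oracle_prob_present_or_f0(kb, d, f, pat@age, params)
    min(max(pp, params@eps_floor), 1 - params@eps_floor)
  }, 0), numeric(length(post)))
  H <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log2(p)) }
  exp_h <- 0
  for (o1 in 0:1) for (o2 in 0:1) for (o3 in 0:1) {
    joint <- (if (o1) pm[, 1] else 1 - pm[, 1]) *
      (if (o2) pm[, 2] else 1 - pm[, 2]) *
      (if (o3) pm[, 3] else 1 - pm[, 3])
    branch <- post * joint
    exp_h <- exp_h + sum(branch) * H(branch)
  }
  expected_gain <- H(post) - exp_h
  expect_equal(got$expected_gain, expected_gain, tolerance = 1e-9)
  expect_equal(got$cost, sum(kb@findings$cost[1:3]))
})

test_that("raising treatability of the leading disease never lowers urgency", {
  kb <- dyadicKB(n_diseases = 10, seed = 42)
  pat <- randomPatient(kb, n_obs = 3, seed = 9)
  s0 <- rankSuggestions(kb, pat, params, top_n = 5)
  lead <- entries(posterior(kb, pat, params))$disease_id[1]
  kb2 <- kb
  i <- match(lead, kb2@diseases$disease_id)
  kb2@diseases$treatability[i] <- 1.0
  s1 <- rankSuggestions(kb2, pat, params, top_n = 5)
  expect_gte(s1$urgency_weight[1], s0$urgency_weight[1])
})
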