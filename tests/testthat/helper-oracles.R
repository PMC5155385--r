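# Independent reference implementations used as oracles. These are written
# as straight-line scalar transcriptions of the model formulas — no log
# space, no vectorized shortcuts — so they share no code path with the
# package internals they check.

oracle_ramp <- function(x, lo, hi) {
  if (lo == hi) return(if (x >= lo) 1 else 0)
  min(max((x - lo) / (hi - lo), 0), 1)
}

oracle_prob_present <- function(freq, olo, ohi, dlo, dhi, age) {
  disap <- if (is.na(dlo)) 0 else oracle_ramp(age, dlo, dhi)
  freq * oracle_ramp(age, olo, ohi) * (1 - disap)
}

oracle_bin_mass <- function(olo, ohi, o, w) {
  a <- o - w / 2; b <- o + w / 2
  if (olo == ohi) return(if (olo >= a && olo <= b) 1 else 0)
  oracle_ramp(b, olo, ohi) - oracle_ramp(a, olo, ohi)
}

# one observation's likelihood under one disease; scalar branch-by-branch
oracle_likelihood <- function(kb, disease_id, finding_id, state, onset_age,
                              age, params) {
  as_ <- associations(kb)
  row <- as_[as_$disease_id == disease_id & as_$finding_id == finding_id, ]
  eps <- params@eps_floor; f0 <- params@f0; bw <- params@bin_width
  if (nrow(row) == 0) {
    if (state == "present" && !is.na(onset_age)) {
      mult <- if (age <= 0) 1 else min(bw / age, 1)
      L <- f0 * mult
    } else if (state == "present") L <- f0
    else L <- 1 - f0
  } else {
    pp <- oracle_prob_present(row$frequency, row$onset_lo, row$onset_hi,
                              row$disap_lo, row$disap_hi, age)
    if (state == "present" && !is.na(onset_age)) {
      disap <- if (is.na(row$disap_lo)) 0 else
        oracle_ramp(age, row$disap_lo, row$disap_hi)
      L <- row$frequency *
        oracle_bin_mass(row$onset_lo, row$onset_hi, onset_age, bw) *
        (1 - disap)
    } else if (state == "present") L <- pp
    else L <- 1 - pp
  }
  max(L, eps)
}

# presence probability with the f0 fallback, no floor
oracle_prob_present_or_f0 <- function(kb, disease_id, finding_id, age,
                                      params) {
  as_ <- associations(kb)
  row <- as_[as_$disease_id == disease_id & as_$finding_id == finding_id, ]
  if (nrow(row) == 0) return(params@f0)
  oracle_prob_present(row$frequency, row$onset_lo, row$onset_hi,
                      row$disap_lo, row$disap_hi, age)
}

oracle_prior <- function(kb, disease_id, age, gender) {
  inc <- incidence(kb)
  ds <- diseases(kb)
  d <- ds[ds$disease_id == disease_id, ]
  w <- NA_real_
  for (i in seq_len(nrow(inc))) {
    if (inc$disease_id[i] != disease_id) next
    if (inc$age_lo[i] <= age &&
        (age < inc$age_hi[i] || (age == 120 && inc$age_hi[i] == 120))) {
      w <- inc$weight[i]
      break
    }
  }
  mult <- if (gender == "male") d$male_mult
  else if (gender == "female") d$female_mult
  else (d$male_mult + d$female_mult) / 2
  w * mult
}

oracle_acuity <- function(kb, disease_id, acuity_obs, params) {
  cls <- diseases(kb)$acuity_class[diseases(kb)$disease_id == disease_id]
  if (cls == "unknown") return(1)
  levs <- c("minutes", "hours", "days", "weeks", "months", "years")
  gap <- abs(match(cls, levs) - match(acuity_obs, levs))
  if (gap == 0) params@acuity_match
  else if (gap == 1) params@acuity_near
  else params@acuity_far
}

# full posterior by direct per-disease products (no log accumulation)
oracle_posterior <- function(kb, patient, params) {
  ds_ids <- diseases(kb)$disease_id
  obs <- observations(patient)
  unnorm <- vapply(ds_ids, function(d) {
    u <- oracle_prior(kb, d, patient@age, patient@gender)
    for (i in seq_len(nrow(obs)))
      u <- u * oracle_likelihood(kb, d, obs$finding_id[i], obs$state[i],
                                 obs$onset_age[i], patient@age, params)
    if (!is.na(patient@acuity))
      u <- u * oracle_acuity(kb, d, patient@acuity, params)
    u
  }, 0)
  p <- unnorm / sum(unnorm)
  names(p) <- ds_ids
  p
}
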