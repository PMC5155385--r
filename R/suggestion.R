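## Value-of-information ranking of unobserved findings and test bundles:
## myopic one-step expected Shannon entropy reduction of the differential,
## weighted by diagnostic urgency (treatability, severity, acuity of the
## leading diseases) and divided by test cost.

## per-disease presence probability of a finding at the patient's age;
## uncurated pairs use f0. clamp keeps branch likelihoods consistent with
## the mixture weight so expected information gain is exactly nonnegative.
.presenceVector <- function(kb, finding_id, age, params, clamp = FALSE) {
  ds_ids <- kb@diseases$disease_id
  rows <- kb@associations[kb@associations$finding_id == finding_id, ,
                          drop = FALSE]
  idx <- match(ds_ids, rows$disease_id)
  p <- rep(params@f0, length(ds_ids))
  cur <- !is.na(idx)
  if (any(cur))
    p[cur] <- probPresentAtAge(rows[idx[cur], , drop = FALSE], age)
  if (clamp)
    p <- pmin(pmax(p, params@eps_floor), 1 - params@eps_floor)
  p
}

.checkUnobserved <- function(finding_id, observed) {
  if (finding_id %in% observed)
    stop(sprintf("finding '%s' already observed", finding_id))
}

#' Predictive probability that an unobserved finding is present
#'
#' Posterior-mixture probability \eqn{\sum_d P(d) \, P(f\ present \mid d)} that
#' the finding would be observed present at the patient's age, using the
#' background rate for uncurated disease-finding pairs.
#'
#' @param kb a \code{\link{KnowledgeBase}}.
#' @param diff the current \code{\link{Differential}}.
#' @param finding_id the candidate finding.
#' @param age patient age in years.
#' @param params an \code{\link{engineParams}} object.
#' @param observed finding ids already observed; an error is raised if the
#'   candidate is among them.
#' @return Probability in [0, 1].
#' @examples
#' kb <- toyKB(); d <- posterior(kb, toyPatient())
#' predictivePresence(kb, d, "conjunctivitis", 8)
#' @export
predictivePresence <- function(kb, diff, finding_id, age,
                               params = engineParams(),
                               observed = character()) {
  .checkUnobserved(finding_id, observed)
  if (!finding_id %in% kb@findings$finding_id)
    stop(sprintf("unknown finding_id '%s'", finding_id))
  p <- .presenceVector(kb, finding_id, age, params)
  e <- diff@entries
  sum(e$posterior * p[match(e$disease_id, kb@diseases$disease_id)])
}

## expected entropy reduction (bits) of jointly observing the findings in
## `members` (2^k outcome tree); post is the posterior vector aligned with
## kb@diseases. Gains below 1e-12 bits are treated as exactly 0.
.jointGainBits <- function(kb, members, post, age, params) {
  k <- length(members)
  pm <- vapply(members, function(f)
    .presenceVector(kb, f, age, params, clamp = TRUE),
    numeric(nrow(kb@diseases)))
  pm <- matrix(pm, ncol = k)
  h0 <- .entropyBits(post)
  exp_h <- 0
  for (pattern in seq_len(2^k) - 1L) {
    joint <- rep(1, length(post))
    for (j in seq_len(k)) {
      present <- bitwAnd(pattern, bitwShiftL(1L, j - 1L)) > 0L
      joint <- joint * if (present) pm[, j] else 1 - pm[, j]
    }
    branch <- post * joint
    q <- sum(branch)
    if (q > 0) exp_h <- exp_h + q * .entropyBits(branch)
  }
  gain <- h0 - exp_h
  if (gain < 1e-12) 0 else gain
}

#' Expected entropy reduction from observing a finding
#'
#' One-step expected information gain, in bits: the Shannon entropy of the
#' current differential minus the expected entropy after observing the
#' finding present or absent, weighted by the predictive presence
#' probability. Never negative.
#'
#' @inheritParams predictivePresence
#' @param patient a \code{\link{PatientProfile}}.
#' @return Expected gain in bits, >= 0.
#' @examples
#' expectedEntropyReduction(toyKB(), toyPatient(), "conjunctivitis")
#' @export
expectedEntropyReduction <- function(kb, patient, finding_id,
                                     params = engineParams()) {
  .checkUnobserved(finding_id, patient@observations$finding_id)
  if (!finding_id %in% kb@findings$finding_id)
    stop(sprintf("unknown finding_id '%s'", finding_id))
  diff <- posterior(kb, patient, params)
  e <- diff@entries
  post <- e$posterior[match(kb@diseases$disease_id, e$disease_id)]
  .jointGainBits(kb, finding_id, post, patient@age, params)
}

#' Rank unobserved findings and bundles by diagnostic usefulness
#'
#' Scores every unobserved finding — and every test bundle whose members are
#' all unobserved — by \code{usefulness = expected_gain * urgency_weight /
#' cost}. The urgency weight grows with the posterior-weighted treatability
#' and severity of the candidate diseases and with the posterior mass on
#' acute diseases (acuity class days or faster):
#' \deqn{u = 1 + w_t \sum_d P(d)\,treat_d + w_s \sum_d P(d)\,sev_d +
#'       w_a \sum_{d\ acute} P(d).}
#' Bundles are scored as a joint observation of their members (full
#' \eqn{2^k} outcome tree; at most 4 members enter the tree, lowest
#' finding_id first) at the summed cost of the scored members.
#'
#' @inheritParams expectedEntropyReduction
#' @param top_n number of suggestions to return.
#' @param w_t,w_s,w_a urgency weights on treatability, severity and acuity
#'   (defaults 1.0, 0.5, 1.0).
#' @return data.frame with columns target_id, kind ("finding" or "bundle"),
#'   expected_gain (bits), urgency_weight, cost, usefulness; sorted by
#'   decreasing usefulness, ties broken by target_id.
#' @examples
#' rankSuggestions(toyKB(), toyPatient(), top_n = 3)
#' @export
rankSuggestions <- function(kb, patient, params = engineParams(),
                            top_n = 10L, w_t = 1.0, w_s = 0.5, w_a = 1.0) {
  observed <- patient@observations$finding_id
  fd <- kb@findings
  unobs <- fd[!fd$finding_id %in% observed, , drop = FALSE]
  if (!nrow(unobs)) stop("no unobserved findings to suggest")

  diff <- posterior(kb, patient, params)
  e <- diff@entries
  ord <- match(kb@diseases$disease_id, e$disease_id)
  post <- e$posterior[ord]
  ds <- kb@diseases
  acute <- ds$acuity_class %in% c("minutes", "hours", "days")
  urgency <- 1 + w_t * sum(post * ds$treatability) +
    w_s * sum(post * ds$severity) + w_a * sum(post[acute])

  rows <- lapply(seq_len(nrow(unobs)), function(i) {
    data.frame(target_id = unobs$finding_id[i], kind = "finding",
               expected_gain = .jointGainBits(kb, unobs$finding_id[i], post,
                                              patient@age, params),
               cost = unobs$cost[i])
  })

  bundles <- unique(unobs$bundle_id[!is.na(unobs$bundle_id)])
  for (b in bundles) {
    members <- fd$finding_id[!is.na(fd$bundle_id) & fd$bundle_id == b]
    if (any(members %in% observed)) next
    members <- sort(members)
    scored <- head(members, 4L)   # outcome tree capped at 4 members
    cost <- sum(fd$cost[match(scored, fd$finding_id)])
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = b, kind = "bundle",
      expected_gain = .jointGainBits(kb, scored, post, patient@age, params),
      cost = cost)
  }

  out <- do.call(rbind, rows)
  out$urgency_weight <- urgency
  out$usefulness <- out$expected_gain * out$urgency_weight / out$cost
  out <- out[order(-out$usefulness, out$target_id, method = "radix"), ,
             drop = FALSE]
  out <- out[, c("target_id", "kind", "expected_gain", "urgency_weight",
                 "cost", "usefulness")]
  rownames(out) <- NULL
  head(out, top_n)
}
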