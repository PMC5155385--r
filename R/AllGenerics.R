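## Accessor generics and show methods.

#' @name accessors
#' @title Accessors for knowledge bases, profiles and differentials
#' @description Slot accessors: \code{findings}, \code{diseases},
#'   \code{associations} and \code{incidence} return the component tables of a
#'   \code{\link{KnowledgeBase}}; \code{categoryNames} the category id-to-name
#'   map and \code{coreChecklist} the core finding ids; \code{observations}
#'   the observation table of a \code{\link{PatientProfile}}; \code{entries}
#'   and \code{logEvidence} the ranked table and evidence of a
#'   \code{\link{Differential}}.
#' @param object a \code{KnowledgeBase}, \code{PatientProfile} or
#'   \code{Differential}.
#' @return The corresponding slot value.
#' @examples
#' kb <- toyKB()
#' nrow(associations(kb))
#' coreChecklist(kb)
NULL

#' @rdname accessors
#' @export
setGeneric("findings", function(object) standardGeneric("findings"))
#' @rdname accessors
#' @export
setGeneric("diseases", function(object) standardGeneric("diseases"))
#' @rdname accessors
#' @export
setGeneric("associations", function(object) standardGeneric("associations"))
#' @rdname accessors
#' @export
setGeneric("incidence", function(object) standardGeneric("incidence"))
#' @rdname accessors
#' @export
setGeneric("categoryNames", function(object) standardGeneric("categoryNames"))
#' @rdname accessors
#' @export
setGeneric("coreChecklist", function(object) standardGeneric("coreChecklist"))
#' @rdname accessors
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))
#' @rdname accessors
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))
#' @rdname accessors
#' @export
setGeneric("logEvidence", function(object) standardGeneric("logEvidence"))

#' @rdname accessors
setMethod("findings", "KnowledgeBase", function(object) object@findings)
#' @rdname accessors
setMethod("diseases", "KnowledgeBase", function(object) object@diseases)
#' @rdname accessors
setMethod("associations", "KnowledgeBase", function(object)
  object@associations)
#' @rdname accessors
setMethod("incidence", "KnowledgeBase", function(object) object@incidence)
#' @rdname accessors
setMethod("categoryNames", "KnowledgeBase", function(object)
  object@categories)
#' @rdname accessors
setMethod("coreChecklist", "KnowledgeBase", function(object)
  object@coreChecklist)
#' @rdname accessors
setMethod("observations", "PatientProfile", function(object)
  object@observations)
#' @rdname accessors
setMethod("entries", "Differential", function(object) object@entries)
#' @rdname accessors
setMethod("logEvidence", "Differential", function(object) object@logEvidence)

setMethod("show", "KnowledgeBase", function(object) {
  cat(sprintf(
    "KnowledgeBase: %d diseases, %d findings, %d associations\n",
    nrow(object@diseases), nrow(object@findings), nrow(object@associations)))
  cat(sprintf("  %d categories; core checklist of %d findings\n",
              length(object@categories), length(object@coreChecklist)))
  if (nrow(object@diseases)) {
    mean_assoc <- nrow(object@associations) / nrow(object@diseases)
    cat(sprintf("  mean findings per disease: %.1f\n", mean_assoc))
  }
})

setMethod("show", "PatientProfile", function(object) {
  obs <- object@observations
  cat(sprintf("PatientProfile: age %.2f y, %s; %d present, %d absent",
              object@age, object@gender, sum(obs$state == "present"),
              sum(obs$state == "absent")))
  if (!is.na(object@acuity)) cat(sprintf("; acuity '%s'", object@acuity))
  cat("\n")
})

setMethod("show", "Differential", function(object) {
  n <- nrow(object@entries)
  cat(sprintf("Differential over %d diseases (log evidence %.4f)\n",
              n, object@logEvidence))
  head_n <- min(5L, n)
  if (head_n) {
    e <- object@entries[seq_len(head_n), ]
    for (i in seq_len(head_n))
      cat(sprintf("  %d. %-20s %.4f\n", i, e$disease_id[i], e$posterior[i]))
    if (n > head_n) cat(sprintf("  ... and %d more\n", n - head_n))
  }
})

setMethod("show", "GEEFit", function(object) {
  cat(sprintf(
    "Logistic GEE (exchangeable): %d obs in %d clusters, alpha = %.4f\n",
    object@n_obs, object@n_clusters, object@alpha))
  if (!object@converged)
    cat(sprintf("  NOT CONVERGED: %s\n", object@status))
  tab <- data.frame(estimate = object@coefficients,
                    robust_se = object@robust_se, wald = object@wald,
                    p = object@p_value)
  print(signif(tab, 4))
})

setMethod("show", "EngineParams", function(object) {
  cat(sprintf(
    "EngineParams: eps_floor=%g, f0=%g, bin_width=%g, acuity=(%g, %g, %g)\n",
    object@eps_floor, object@f0, object@bin_width, object@acuity_match,
    object@acuity_near, object@acuity_far))
})
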