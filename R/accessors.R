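#' Accessors for cohort and fit objects
#'
#' Slot accessors for \linkS4class{SyntheticCohort}, \linkS4class{SHMTFit}
#' and \linkS4class{HormesisFit}; preferred over direct slot access.
#'
#' @param x a \linkS4class{SyntheticCohort}, \linkS4class{SHMTFit} or
#'   \linkS4class{HormesisFit}.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortGenome", function(x) standardGeneric("cohortGenome"))
#' @rdname accessors
#' @export
setMethod("cohortGenome", "SyntheticCohort", function(x) x@genome)

#' @rdname accessors
#' @export
setGeneric("cohortGenes", function(x) standardGeneric("cohortGenes"))
#' @rdname accessors
#' @export
setMethod("cohortGenes", "SyntheticCohort", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("cohortTruthGenotypes", function(x) standardGeneric("cohortTruthGenotypes"))
#' @rdname accessors
#' @export
setMethod("cohortTruthGenotypes", "SyntheticCohort", function(x) x@truthGenotypes)

#' @rdname accessors
#' @export
setGeneric("cohortCounts", function(x) standardGeneric("cohortCounts"))
#' @rdname accessors
#' @export
setMethod("cohortCounts", "SyntheticCohort", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("cohortSheet", function(x) standardGeneric("cohortSheet"))
#' @rdname accessors
#' @export
setMethod("cohortSheet", "SyntheticCohort", function(x) x@sheet)

#' @rdname accessors
#' @export
setGeneric("fitD0", function(x) standardGeneric("fitD0"))
#' @rdname accessors
#' @export
setMethod("fitD0", "SHMTFit", function(x) x@D0)

#' @rdname accessors
#' @export
setGeneric("fitN", function(x) standardGeneric("fitN"))
#' @rdname accessors
#' @export
setMethod("fitN", "SHMTFit", function(x) x@N)

#' @rdname accessors
#' @export
setGeneric("fitDq", function(x) standardGeneric("fitDq"))
#' @rdname accessors
#' @export
setMethod("fitDq", "SHMTFit", function(x) x@Dq)

#' @rdname accessors
#' @export
setGeneric("fitLD50", function(x) standardGeneric("fitLD50"))
#' @rdname accessors
#' @export
setMethod("fitLD50", "SHMTFit", function(x) x@LD50)

#' @rdname accessors
#' @export
setGeneric("fitRSS", function(x) standardGeneric("fitRSS"))
#' @rdname accessors
#' @export
setMethod("fitRSS", "SHMTFit", function(x) x@rss)
#' @rdname accessors
#' @export
setMethod("fitRSS", "HormesisFit", function(x) x@rss)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort\n")
  cat("  genome:", length(object@genome), "chromosome(s),",
      sum(Biostrings::width(object@genome)), "bp\n")
  cat("  genes:", sum(object@genes$type == "gene"), "\n")
  cat("  truth mutations:", nrow(object@truth), "\n")
  cat("  samples:", nrow(object@sheet),
      sprintf("(%d control)", sum(object@sheet$role == "control")), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "SHMTFit", function(object) {
  cat("Single-hit multi-target fit\n")
  cat(sprintf("  D0 = %.3f Gy, N = %.3f\n", object@D0, object@N))
  cat(sprintf("  Dq = %.2f Gy, LD50 = %.2f Gy\n", object@Dq, object@LD50))
  cat(sprintf("  RSS = %.4g, converged = %s\n", object@rss, object@converged))
})

setMethod("show", "HormesisFit", function(object) {
  cat("Brain-Cousens hormesis fit",
      if (object@fallback) "(monotone fallback, f = 0)" else "", "\n")
  cat(sprintf("  b = %.3f, c = %.3f, d = %.3f, e = %.3f, f = %.4f\n",
              object@b, object@c, object@d, object@e, object@f))
  cat(sprintf("  RSS = %.4g, converged = %s\n", object@rss, object@converged))
})
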