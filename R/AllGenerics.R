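#' Variant identifiers of an object
#' @param x An object carrying variant identifiers.
#' @return Character vector.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname variantIds
#' @export
setMethod("variantIds", "LdReference", function(x) x@variantIds)

#' Signed LD correlation matrix
#' @param x An [LdReference-class] object.
#' @param squared Return r-squared instead of signed r.
#' @return Numeric matrix.
#' @export
setGeneric("ldMatrix", function(x, squared = FALSE) standardGeneric("ldMatrix"))

#' @rdname ldMatrix
#' @export
setMethod("ldMatrix", "LdReference", function(x, squared = FALSE) {
  if (squared) x@r^2 else x@r
})

#' Posterior probabilities of the five colocalization hypotheses
#' @param x A [ColocResult-class] object.
#' @return Named numeric of length five (`PP0`..`PP4`).
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' @rdname posteriors
#' @export
setMethod("posteriors", "ColocResult", function(x) x@pp)

#' Number of variants used in a result
#' @param x A result object.
#' @return Integer.
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname nSnps
#' @export
setMethod("nSnps", "ColocResult", function(x) x@nSnps)
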