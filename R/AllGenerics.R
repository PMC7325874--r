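#' @rdname CodonProfileSet-class
#' @param x,object A `CodonProfileSet`.
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("replicateNames", function(x) standardGeneric("replicateNames"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("profileDensities",
           function(x) standardGeneric("profileDensities"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname CodonProfileSet-class
#' @export
setGeneric("removalLog", function(x) standardGeneric("removalLog"))

#' Compute the ribosome density index
#'
#' `computeRdi()` evaluates
#' \deqn{RDI = \sum_{i=1}^{n} i\,d_i \; / \; (n \sum_{i=1}^{n} d_i)}
#' with 1-based codon index \eqn{i}, for a numeric per-codon profile or
#' for every profile of a [CodonProfileSet] (densities when the set is
#' normalized, raw counts otherwise; RDI is invariant to the per-transcript
#' scale so both give identical values). For any profile with positive
#' total density, \eqn{1/n \le RDI \le 1}; a uniform profile gives
#' \eqn{(n+1)/(2n)}.
#'
#' @param x A non-negative numeric vector with positive sum, or a
#'   `CodonProfileSet`.
#' @param ... Passed to methods.
#' @return A single RDI value for a numeric vector; for a
#'   `CodonProfileSet`, a numeric vector with one RDI per profile (named
#'   `transcript|condition|replicate`).
#' @examples
#' computeRdi(rep(1, 10))          # uniform: (n+1)/(2n) = 0.55
#' computeRdi(c(3, 2, 1, 0))       # 5' skewed: 10/24
#' @export
setGeneric("computeRdi", function(x, ...) standardGeneric("computeRdi"))

#' @rdname CodonUsageTable-class
#' @param x,object A `CodonUsageTable`.
#' @export
setGeneric("codonW", function(x) standardGeneric("codonW"))

#' @rdname CodonUsageTable-class
#' @export
setGeneric("codonAbundance",
           function(x) standardGeneric("codonAbundance"))
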