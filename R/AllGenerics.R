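#' @rdname SwarmDomain-class
#' @param object a \code{SwarmDomain}
#' @export
setGeneric("domainTau", function(object) standardGeneric("domainTau"))

#' @rdname SwarmDomain-class
#' @export
setGeneric("domainShifts", function(object) standardGeneric("domainShifts"))

#' @rdname SwarmDomain-class
#' @export
setGeneric("domainExtent", function(object) standardGeneric("domainExtent"))

#' @rdname SwarmBasis-class
#' @param object a \code{SwarmBasis}
#' @export
setGeneric("basisSize", function(object) standardGeneric("basisSize"))

#' @rdname SwarmBasis-class
#' @export
setGeneric("constantValue", function(object) standardGeneric("constantValue"))

#' @rdname SpectralFit-class
#' @param object a \code{SpectralFit}
#' @export
setGeneric("spectralCoefficients",
  function(object) standardGeneric("spectralCoefficients"))

#' @rdname SpectralFit-class
#' @export
setGeneric("rescaledCoefficients",
  function(object) standardGeneric("rescaledCoefficients"))

#' @rdname SpectralFit-class
#' @export
setGeneric("patternScores", function(object) standardGeneric("patternScores"))

#' @rdname SpectralFit-class
#' @export
setGeneric("selectedGenes", function(object) standardGeneric("selectedGenes"))

setMethod("domainTau", "SwarmDomain", function(object) object@tau)
setMethod("domainShifts", "SwarmDomain", function(object) object@timeShifts)
setMethod("domainExtent", "SwarmDomain", function(object) object@Tmax)

setMethod("basisSize", "SwarmBasis", function(object) object@M)
setMethod("constantValue", "SwarmBasis",
  function(object) object@coefficients[1L, 1L])

setMethod("spectralCoefficients", "SpectralFit",
  function(object) object@coefficients)
setMethod("rescaledCoefficients", "SpectralFit", function(object) object@rescaled)
setMethod("patternScores", "SpectralFit", function(object) object@scores)
setMethod("selectedGenes", "SpectralFit", function(object) {
  rownames(object@scores)[object@scores$selected]
})

setMethod("show", "SwarmDomain", function(object) {
  cat("SwarmDomain: shared exponential boundary fit\n")
  cat(sprintf("  tau        : %.4f h\n", object@tau))
  cat(sprintf("  replicates : %s\n",
    paste(sprintf("%s (b0 = %.3f mm)", names(object@b0), object@b0),
          collapse = ", ")))
  cat(sprintf("  reference  : %s  (b0 common = %.3f mm)\n",
    object@reference, object@b0Common))
  cat(sprintf("  T (common non-dimensional extent): %.4f\n", object@Tmax))
})

setMethod("show", "SwarmBasis", function(object) {
  cat("SwarmBasis: orthonormal polynomials on the swarm domain\n")
  cat(sprintf("  T = %.4f, %d basis functions (M = %d)\n",
    object@Tmax, object@M + 1L, object@M))
  cat(sprintf("  quadrature: %d x %d Gauss-Legendre nodes\n",
    object@nodeCounts[1L], object@nodeCounts[2L]))
  cat(sprintf("  P0 = %.6f (constant)\n", constantValue(object)))
})

setMethod("show", "SpectralFit", function(object) {
  sc <- object@scores
  cat("SpectralFit\n")
  cat(sprintf("  %d genes, %d basis functions\n",
    nrow(sc), ncol(object@coefficients)))
  cat(sprintf("  constant genes (excluded from scoring): %d\n",
    sum(sc$constant)))
  cat(sprintf("  selected as spatiotemporally patterned : %d\n",
    sum(sc$selected)))
})

setMethod("show", "SwarmAnalysis", function(object) {
  cat("SwarmAnalysis (transcriptome pipeline run)\n")
  cat(sprintf("  %d genes x %d samples after filtering\n",
    nrow(object@se), ncol(object@se)))
  show(object@domain)
  cat(sprintf("  selected genes: %d", sum(object@fit@scores$selected)))
  if (length(object@clustering))
    cat(sprintf("; clusters: %d",
      length(unique(object@clustering$labels))))
  cat("\n")
})
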