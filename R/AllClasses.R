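#' @import methods
#' @importFrom stats approx dist hclust cutree median optimize quantile rnbinom
#'   rnorm rpois runif sd setNames cmdscale cor
#' @importFrom utils head
NULL

#' Shared exponential swarm domain
#'
#' A \code{SwarmDomain} holds the result of jointly fitting an exponentially
#' expanding colony boundary \eqn{b(t) = b_0 e^{t/\tau}} to all replicates
#' with a single shared growth timescale \eqn{\tau} and per-replicate
#' intercepts, together with the per-replicate time shifts that map every
#' replicate onto one common non-dimensional space-time domain
#' \eqn{\{0 \le \tilde t \le T,\; 0 \le \tilde p \le e^{\tilde t}\}}.
#'
#' @slot tau shared growth timescale in hours.
#' @slot b0 named numeric, fitted initial radius (mm) per replicate.
#' @slot timeShifts named numeric, per-replicate time shift (h).
#' @slot b0Common common radius scale (mm) used to non-dimensionalise
#'   radial positions.
#' @slot Tmax maximum non-dimensional time present in all replicates.
#' @slot reference id of the reference replicate (largest \code{b0}).
#'
#' @seealso [fitBoundary()], [nondimensionalize()]
#' @export
setClass("SwarmDomain",
  representation(
    tau = "numeric",
    b0 = "numeric",
    timeShifts = "numeric",
    b0Common = "numeric",
    Tmax = "numeric",
    reference = "character"
  )
)

setValidity("SwarmDomain", function(object) {
  msg <- character()
  if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau <= 0)
    msg <- c(msg, "'tau' must be a single positive number")
  if (any(object@b0 <= 0)) msg <- c(msg, "all 'b0' must be positive")
  if (!identical(names(object@b0), names(object@timeShifts)))
    msg <- c(msg, "'b0' and 'timeShifts' must share replicate names")
  if (length(object@Tmax) == 1L && is.finite(object@Tmax) &&
      object@Tmax <= 0)
    msg <- c(msg, "'Tmax' must be positive")
  if (length(object@reference) == 1L &&
      !(object@reference %in% names(object@b0)))
    msg <- c(msg, "'reference' must name one of the replicates")
  # the reference replicate must reproduce the common scale:
  # b0Common = b0^(r) * exp(t_s^(r) / tau)
  if (length(msg) == 0L) {
    r <- object@reference
    expect <- object@b0[[r]] * exp(object@timeShifts[[r]] / object@tau)
    if (abs(expect - object@b0Common) > 1e-6 * max(1, object@b0Common))
      msg <- c(msg, "b0Common inconsistent with reference replicate")
  }
  if (length(msg)) msg else TRUE
})

#' Orthonormal polynomial basis on the swarm domain
#'
#' A \code{SwarmBasis} stores the polynomial system obtained by Gram-Schmidt
#' orthogonalisation of the graded monomials
#' \eqn{1, \tilde t, \tilde p, \tilde t^2, \tilde t\tilde p, \tilde p^2,
#' \dots} under the weighted inner product
#' \deqn{\langle f, g\rangle = \int_0^T \mathrm{d}\tilde t
#'   \int_0^{e^{\tilde t}} \mathrm{d}\tilde p\; e^{-\tilde t} f g.}
#' Each basis function is represented by its coefficients on the monomials,
#' so evaluation anywhere in the domain is exact; the quadrature nodes and
#' weights used for the orthogonalisation are retained for reproducibility.
#'
#' @slot Tmax domain extent in non-dimensional time.
#' @slot M highest basis index; the basis holds \code{M + 1} functions.
#' @slot exponents integer matrix, one row per monomial, columns are the
#'   powers of \eqn{\tilde t} and \eqn{\tilde p} in graded order.
#' @slot coefficients numeric matrix, row \code{m + 1} holds the monomial
#'   coefficients of basis function \eqn{P_m}.
#' @slot nodes two-column matrix of quadrature nodes \eqn{(\tilde t, \tilde p)}.
#' @slot weights quadrature weights (the \eqn{e^{-\tilde t}} weight folded in).
#' @slot nodeCounts integer pair: node counts along \eqn{\tilde t} and
#'   \eqn{\tilde p}.
#'
#' @seealso [swarmBasis()], [evaluateDesign()]
#' @export
setClass("SwarmBasis",
  representation(
    Tmax = "numeric",
    M = "integer",
    exponents = "matrix",
    coefficients = "matrix",
    nodes = "matrix",
    weights = "numeric",
    nodeCounts = "integer"
  )
)

setValidity("SwarmBasis", function(object) {
  msg <- character()
  if (object@Tmax <= 0) msg <- c(msg, "'Tmax' must be positive")
  if (object@M < 0L) msg <- c(msg, "'M' must be non-negative")
  if (nrow(object@coefficients) != object@M + 1L)
    msg <- c(msg, "'coefficients' must have M + 1 rows")
  if (ncol(object@coefficients) != nrow(object@exponents))
    msg <- c(msg, "'coefficients' columns must match monomial count")
  if (any(object@weights <= 0)) msg <- c(msg, "quadrature weights must be positive")
  if (length(msg)) msg else TRUE
})

#' Spectral representation of a gene (or phenotype) cohort
#'
#' A \code{SpectralFit} bundles, for every gene, the stacked-replicate
#' least-squares coefficients on the domain basis, the standardised
#' ("rescaled") coefficients used for pattern comparison, and the pattern
#' scores: representation error \eqn{\mathcal{E}}, pattern energy
#' \eqn{\mathcal{P}} and ranking \eqn{\mathcal{R} = \mathcal{P}/\mathcal{E}},
#' together with the weighted-median selection flag.
#'
#' @slot coefficients gene-by-basis matrix of raw stacked coefficients.
#' @slot rescaled gene-by-basis matrix of standardised coefficients; rows for
#'   constant genes are \code{NA}.
#' @slot mu,sigma per-gene mean and standard deviation of expression over the
#'   in-domain samples.
#' @slot scores data.frame with columns \code{E}, \code{P}, \code{R},
#'   \code{selected}, \code{constant}, one row per gene.
#' @slot basis the [SwarmBasis] the coefficients refer to.
#'
#' @seealso [fitSpectral()], [patternScores()], [selectPatterned()]
#' @export
setClass("SpectralFit",
  representation(
    coefficients = "matrix",
    rescaled = "matrix",
    mu = "numeric",
    sigma = "numeric",
    scores = "data.frame",
    basis = "SwarmBasis"
  )
)

setValidity("SpectralFit", function(object) {
  msg <- character()
  if (nrow(object@coefficients) != nrow(object@scores))
    msg <- c(msg, "'coefficients' and 'scores' must have one row per gene")
  if (!all(c("E", "P", "R", "selected", "constant") %in% names(object@scores)))
    msg <- c(msg, "'scores' must have columns E, P, R, selected, constant")
  if (length(msg)) msg else TRUE
})

#' End-to-end transcriptome analysis bundle
#'
#' Returned by [runTranscriptomeAnalysis()]; holds every intermediate of the
#' pipeline (filtered counts, normalised expression, domain fit, basis,
#' spectral fit, clustering and embedding) plus the parameters used, so a
#' run can be inspected, reported on, and reproduced.
#'
#' @slot se \linkS4class{SummarizedExperiment} with assays \code{counts} and
#'   \code{logexpr} on the filtered genes/samples; \code{colData} holds the
#'   sample annotations and scaled coordinates.
#' @slot domain the fitted [SwarmDomain].
#' @slot basis the [SwarmBasis].
#' @slot fit the [SpectralFit] for all genes.
#' @slot clustering list with elements \code{labels}, \code{medoids},
#'   \code{representatives}, \code{cost}, \code{elbow} (or empty if fewer
#'   selected genes than clusters).
#' @slot mds list with \code{coords} and \code{stress}.
#' @slot params list of all pipeline parameters (including seeds).
#'
#' @export
setClass("SwarmAnalysis",
  representation(
    se = "ANY",
    domain = "SwarmDomain",
    basis = "SwarmBasis",
    fit = "SpectralFit",
    clustering = "list",
    mds = "list",
    params = "list"
  )
)
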