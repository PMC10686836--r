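#' Run the transcriptome analysis pipeline end to end
#'
#' Executes the fixed stage order: gene filter, sample filter, TMM
#' normalisation, log2 transform, domain fit, non-dimensionalisation,
#' stacked spectral fit, pattern scoring and selection, cosine similarity,
#' k-medoids clustering and MDS embedding. Every intermediate is kept on
#' the returned [SwarmAnalysis]; a rerun with the same inputs and
#' parameters is bit-identical.
#'
#' @param counts gene-by-sample count matrix.
#' @param annotations data.frame with one row per sample (matched by
#'   \code{sample_id} against the count columns) carrying \code{replicate},
#'   \code{time} and \code{position}.
#' @param boundaryObs boundary observations for [fitBoundary()], or an
#'   already fitted [SwarmDomain].
#' @param M basis size index (default 5).
#' @param nNodes quadrature node counts (default 64 x 64).
#' @param minReads,minSamples gene filter thresholds.
#' @param minTotal sample filter threshold.
#' @param pseudocount for the log2 transform.
#' @param k number of pattern clusters (default 6).
#' @param elbowRange cluster counts for the elbow curve (default 2:12;
#'   \code{NULL} skips it).
#' @param seed integer seed, recorded in the parameters (the pipeline is
#'   deterministic, the seed is provenance).
#' @return a [SwarmAnalysis].
#' @export
runTranscriptomeAnalysis <- function(counts, annotations, boundaryObs,
                                     M = 5L, nNodes = c(64L, 64L),
                                     minReads = 10L, minSamples = 2L,
                                     minTotal = 1e6, pseudocount = 0.5,
                                     k = 6L, elbowRange = 2:12,
                                     seed = 1L) {
  ann <- as.data.frame(annotations)
  stopifnot(all(c("sample_id", "replicate", "time", "position") %in%
                  names(ann)))
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% ann$sample_id))
    stop("count columns without matching annotation")
  ann <- ann[match(colnames(counts), ann$sample_id), ]

  counts <- filterGenes(counts, minReads, minSamples)
  counts <- filterSamples(counts, minTotal)
  ann <- ann[match(colnames(counts), ann$sample_id), ]

  factors <- tmmFactors(counts)
  logexpr <- normalizedLog2(counts, factors, pseudocount)

  domain <- if (is(boundaryObs, "SwarmDomain")) boundaryObs else
    fitBoundary(boundaryObs)
  ann <- nondimensionalize(ann, domain)
  keep <- ann$in_domain
  anni <- ann[keep, , drop = FALSE]
  expri <- logexpr[, keep, drop = FALSE]

  basis <- swarmBasis(domain@Tmax, M = M, nNodes = nNodes)
  reps <- unique(anni$replicate)
  designs <- lapply(reps, function(r) {
    evaluateDesign(basis,
                   anni[anni$replicate == r, c("t_tilde", "p_tilde")])
  })
  exprs <- lapply(reps, function(r)
    expri[, anni$replicate == r, drop = FALSE])
  design <- do.call(rbind, designs)
  exprStacked <- do.call(cbind, exprs)
  fit <- spectralFit(exprStacked, design, basis)

  clustering <- list()
  mds <- list()
  sel <- fit@scores$selected & !fit@scores$constant
  if (sum(sel) >= k) {
    ksel <- fit@rescaled[sel, , drop = FALSE]
    sim <- cosineSimilarity(ksel)
    keepSim <- setdiff(rownames(ksel), attr(sim, "dropped"))
    Rsel <- fit@scores$R[sel]
    names(Rsel) <- rownames(ksel)
    clustering <- clusterPatterns(sim, k, R = Rsel[rownames(sim)])
    if (!is.null(elbowRange))
      clustering$elbow <- elbowCurve(sim, elbowRange)
    mds <- mdsEmbed(sim)
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, logexpr = unclass(logexpr)),
    colData = S4Vectors::DataFrame(ann, row.names = ann$sample_id))
  SummarizedExperiment::colData(se)$norm_factor <- factors

  new("SwarmAnalysis", se = se, domain = domain, basis = basis, fit = fit,
      clustering = clustering, mds = mds,
      params = list(M = M, nNodes = nNodes, minReads = minReads,
                    minSamples = minSamples, minTotal = minTotal,
                    pseudocount = pseudocount, k = k, seed = seed))
}

#' Run phenotype properties through the spectral pipeline
#'
#' Phenotype heat maps use the identical spectral representation and
#' scoring path as the genes: per-property sample vectors are fitted on
#' the stacked replicate designs, standardised, scored and selected.
#'
#' @param properties property-by-sample matrix of per-video scalars
#'   (columns matched to \code{annotations$sample_id}).
#' @param annotations sample annotations including \code{replicate},
#'   \code{time}, \code{position}.
#' @param domain a [SwarmDomain].
#' @param basis a [SwarmBasis] (defaults to building one on the domain).
#' @return a [SpectralFit] for the properties.
#' @export
runPhenotypeAnalysis <- function(properties, annotations, domain,
                                 basis = NULL) {
  properties <- as.matrix(properties)
  ann <- nondimensionalize(as.data.frame(annotations), domain)
  if (!is.null(ann$sample_id) && !is.null(colnames(properties)))
    ann <- ann[match(colnames(properties), ann$sample_id), ]
  keep <- ann$in_domain
  anni <- ann[keep, , drop = FALSE]
  prop <- properties[, keep, drop = FALSE]
  if (is.null(basis)) basis <- swarmBasis(domain@Tmax)
  reps <- unique(anni$replicate)
  design <- do.call(rbind, lapply(reps, function(r)
    evaluateDesign(basis,
                   anni[anni$replicate == r, c("t_tilde", "p_tilde")])))
  prop <- do.call(cbind, lapply(reps, function(r)
    prop[, anni$replicate == r, drop = FALSE]))
  spectralFit(prop, design, basis)
}

#' Human-readable summary of a pipeline run
#'
#' @param analysis a [SwarmAnalysis].
#' @param genes optional gene ids whose dynamic ranges are reported.
#' @return list (suitable for JSON) with gene/sample counts surviving the
#'   filters, the selection size, cluster sizes, the elbow curve, dynamic
#'   ranges for the named genes, and all parameters; a markdown rendering
#'   is attached as attribute \code{"markdown"}.
#' @export
analysisReport <- function(analysis, genes = character()) {
  sc <- analysis@fit@scores
  logexpr <- SummarizedExperiment::assay(analysis@se, "logexpr")
  dr <- vapply(intersect(genes, rownames(logexpr)), function(g)
    dynamicRange(logexpr[g, ]), 0)
  clusterSizes <- if (length(analysis@clustering))
    as.list(table(analysis@clustering$labels)) else list()
  rep <- list(
    n_genes = nrow(analysis@se),
    n_samples = ncol(analysis@se),
    n_in_domain = sum(SummarizedExperiment::colData(analysis@se)$in_domain),
    tau = analysis@domain@tau,
    Tmax = analysis@domain@Tmax,
    n_constant = sum(sc$constant),
    n_selected = sum(sc$selected),
    cluster_sizes = clusterSizes,
    elbow = if (!is.null(analysis@clustering$elbow))
      analysis@clustering$elbow else NULL,
    mds_stress = if (length(analysis@mds)) analysis@mds$stress else NULL,
    dynamic_ranges = as.list(dr),
    params = analysis@params
  )
  md <- c(
    "# Swarm spatiotemporal analysis report",
    "",
    sprintf("- genes surviving filters: %d", rep$n_genes),
    sprintf("- samples surviving filters: %d (%d in-domain)",
            rep$n_samples, rep$n_in_domain),
    sprintf("- fitted growth timescale tau: %.4f h", rep$tau),
    sprintf("- common domain extent T: %.4f", rep$Tmax),
    sprintf("- genes selected as spatiotemporally patterned: %d",
            rep$n_selected),
    if (length(clusterSizes))
      sprintf("- cluster sizes: %s",
              paste(unlist(clusterSizes), collapse = ", "))
    else "- no clustering (selection smaller than k)",
    sprintf("- parameters: M = %d, k = %d, seed = %d",
            rep$params$M, rep$params$k, rep$params$seed)
  )
  attr(rep, "markdown") <- paste(md, collapse = "\n")
  rep
}
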