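#' Standardise spectral coefficients for pattern comparison
#'
#' Makes coefficient vectors comparable across genes regardless of each
#' gene's overall expression level and scale:
#' \deqn{k_m = \frac{c_m - \delta_{m,0}\,\mu / p_0}{\sigma}}
#' i.e. the gene mean (expressed in units of the constant basis function
#' \eqn{P_0 = p_0}) is subtracted from the constant coefficient only, and
#' all coefficients are divided by the gene's standard deviation. After
#' this rescaling \eqn{k_0} is no longer an independent parameter. Genes
#' with zero standard deviation are flagged constant and excluded from
#' scoring (their rescaled rows are \code{NA}).
#'
#' @param coefficients gene-by-basis matrix of raw (stacked) coefficients.
#' @param expression gene-by-sample matrix of the in-domain expression
#'   values the coefficients were fitted to (all replicates pooled), used
#'   for the per-gene mean and standard deviation.
#' @param p0 value of the constant basis function, see [constantValue()].
#' @return list with \code{k} (rescaled matrix), \code{mu}, \code{sigma},
#'   \code{constant} (logical flag per gene).
#' @export
rescaleCoefficients <- function(coefficients, expression, p0) {
  coefficients <- as.matrix(coefficients)
  expression <- as.matrix(expression)
  stopifnot(nrow(coefficients) == nrow(expression))
  mu <- rowMeans(expression)
  sigma <- apply(expression, 1L, sd)
  constant <- sigma == 0 | !is.finite(sigma)
  k <- coefficients
  k[, 1L] <- k[, 1L] - mu / p0
  k <- k / sigma
  k[constant, ] <- NA_real_
  list(k = k, mu = mu, sigma = sigma, constant = constant)
}

#' Score genes for spatiotemporal patterning
#'
#' For each gene, computes the standardised representation error
#' \deqn{\mathcal{E} = \left\| \frac{g - \mu}{\sigma} -
#'   \sum_m k_m P_m \right\|^2,} the pattern energy
#' \eqn{\mathcal{P} = \sum_{m \ge 1} k_m^2} and the space-time ranking
#' \eqn{\mathcal{R} = \mathcal{P} / \mathcal{E}}. A gene represented
#' exactly by the basis (\eqn{\mathcal{E} = 0}) gets \eqn{\mathcal{R} =
#' \infty} and ranks top. \eqn{\mathcal{R}} is invariant under per-gene
#' shifts and positive scalings of expression.
#'
#' @param expression gene-by-sample matrix of in-domain values (replicates
#'   stacked, columns aligned with \code{design} rows).
#' @param coefficients raw gene-by-basis coefficient matrix fitted to
#'   \code{expression}.
#' @param design stacked design matrix from [evaluateDesign()].
#' @param rescaled output of [rescaleCoefficients()]; computed when absent.
#' @param p0 constant basis value, required if \code{rescaled} is absent.
#' @return data.frame with columns \code{E}, \code{P}, \code{R},
#'   \code{constant}, one row per gene.
#' @export
scorePatterns <- function(expression, coefficients, design,
                          rescaled = NULL, p0 = NULL) {
  expression <- as.matrix(expression)
  coefficients <- as.matrix(coefficients)
  if (is.null(rescaled)) {
    if (is.null(p0)) stop("supply 'p0' when 'rescaled' is not given")
    rescaled <- rescaleCoefficients(coefficients, expression, p0)
  }
  resid <- expression - coefficients %*% t(design)
  E <- rowSums(resid^2) / rescaled$sigma^2
  P <- rowSums(rescaled$k[, -1L, drop = FALSE]^2)
  # a standardised residual at round-off level means the gene is exactly
  # representable in the basis: rank it top with an infinite sentinel
  exact <- E < 1e-12 * ncol(expression)
  R <- ifelse(exact, Inf, P / E)
  E[rescaled$constant] <- NA_real_
  P[rescaled$constant] <- NA_real_
  R[rescaled$constant] <- NA_real_
  data.frame(E = E, P = P, R = R, constant = rescaled$constant,
             row.names = rownames(expression))
}

#' Select spatiotemporally patterned genes (weighted-median cut-off)
#'
#' Orders genes by ranking \eqn{\mathcal{R}} from smallest to largest and
#' finds the largest integer \eqn{N_c} such that the cumulative fraction
#' \eqn{\sum_{n \le N_c} \mathcal{R}_n / \sum_n \mathcal{R}_n \le 0.5};
#' genes ranked above \eqn{N_c} are selected, so the selected genes jointly
#' carry at least half of the total ranking. Infinite rankings (perfectly
#' represented genes) are always selected but excluded from the cumulative
#' denominator; constant genes (\code{NA} ranking) are never selected.
#'
#' @param R numeric vector of rankings (may contain \code{Inf} and
#'   \code{NA}).
#' @return logical selection vector aligned with \code{R}.
#' @export
selectPatterned <- function(R) {
  selected <- rep(FALSE, length(R))
  names(selected) <- names(R)
  inf <- is.infinite(R) & R > 0
  fin <- is.finite(R)
  selected[inf] <- TRUE
  total <- sum(R[fin])
  if (!any(fin) || total == 0) return(selected)
  ord <- order(R[fin])                     # smallest to largest
  frac <- cumsum(R[fin][ord]) / total
  Nc <- max(0L, suppressWarnings(max(which(frac <= 0.5))))
  if (is.infinite(Nc)) Nc <- 0L
  idx <- which(fin)[ord]
  if (Nc < length(idx)) selected[idx[(Nc + 1L):length(idx)]] <- TRUE
  selected
}

#' Assemble a full spectral fit with scores and selection
#'
#' Convenience constructor running [rescaleCoefficients()],
#' [scorePatterns()] and [selectPatterned()] on a stacked fit.
#'
#' @param expression gene-by-sample matrix (replicates stacked, in-domain).
#' @param design stacked design matrix.
#' @param basis the [SwarmBasis].
#' @return a [SpectralFit].
#' @export
spectralFit <- function(expression, design, basis) {
  coefs <- fitSpectral(expression, design)
  rs <- rescaleCoefficients(coefs, expression, constantValue(basis))
  sc <- scorePatterns(expression, coefs, design, rescaled = rs)
  sc$selected <- selectPatterned(sc$R)
  new("SpectralFit", coefficients = coefs, rescaled = rs$k,
      mu = rs$mu, sigma = rs$sigma, scores = sc, basis = basis)
}

#' Cosine similarity between pattern coefficient vectors
#'
#' \deqn{d_{np} = \frac{\sum_{m \ge 1} k_{m,n} k_{m,p}}
#'   {\sqrt{\sum_{m \ge 1} k_{m,n}^2}\,\sqrt{\sum_{m \ge 1} k_{m,p}^2}}}
#' The constant coefficient (\eqn{m = 0}) is excluded so the similarity
#' captures the shape of the spatiotemporal pattern, independent of level
#' and scale. Genes with a zero pattern vector are dropped with a warning.
#'
#' @param k gene-by-basis matrix of rescaled coefficients (selected genes).
#' @return symmetric similarity matrix with unit diagonal; dropped genes
#'   recorded in attribute \code{"dropped"}.
#' @export
cosineSimilarity <- function(k) {
  k <- as.matrix(k)[, -1L, drop = FALSE]
  nrm <- sqrt(rowSums(k^2))
  bad <- nrm == 0 | !is.finite(nrm)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero pattern vector excluded")
    k <- k[!bad, , drop = FALSE]
    nrm <- nrm[!bad]
  }
  S <- tcrossprod(k / nrm)
  S[S > 1] <- 1; S[S < -1] <- -1
  diag(S) <- 1
  attr(S, "dropped") <- names(bad)[bad]
  S
}

#' Cluster patterned genes by k-medoids (PAM)
#'
#' Partitions genes around medoids on the cosine distance
#' \eqn{1 - d_{np}}, using the PAM build + swap algorithm. The medoid of a
#' cluster is the member minimising the summed distance to the others; if
#' rankings are supplied, each cluster's representative is additionally
#' reported as its highest-ranked gene.
#'
#' @param similarity cosine similarity matrix from [cosineSimilarity()].
#' @param k number of clusters (at least 2, at most the number of genes).
#' @param R optional ranking vector (named or aligned) for choosing
#'   representatives.
#' @return list with \code{labels} (named integer vector), \code{medoids},
#'   \code{representatives} (highest-ranked member per cluster, if \code{R}
#'   given), and \code{cost} (total distance to assigned medoids).
#' @export
clusterPatterns <- function(similarity, k, R = NULL) {
  n <- nrow(similarity)
  if (k > n) stop("more clusters than genes")
  D <- 1 - similarity
  ids <- rownames(similarity)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == n) {
    labels <- seq_len(n); names(labels) <- ids
    return(list(labels = labels, medoids = ids,
                representatives = ids, cost = 0))
  }
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  labels <- fit$clustering
  names(labels) <- ids
  medoids <- ids[fit$id.med]
  cost <- sum(D[cbind(seq_len(n), fit$id.med[labels])])
  reps <- NULL
  if (!is.null(R)) {
    if (!is.null(names(R))) R <- R[ids]
    reps <- vapply(seq_len(k), function(cl) {
      members <- which(labels == cl)
      ids[members[which.max(R[members])]]
    }, "")
  }
  list(labels = labels, medoids = medoids, representatives = reps,
       cost = cost)
}

#' Total k-medoids cost versus number of clusters
#'
#' Computes the total within-cluster distance for each candidate \code{k};
#' the elbow of this non-increasing curve guides the choice of the number
#' of pattern clusters (the analysis default is 6). The curvature-based
#' suggestion (discrete second difference) is attached for convenience;
#' the choice itself is left to the caller.
#'
#' @param similarity cosine similarity matrix.
#' @param kRange integer vector of cluster counts to evaluate.
#' @return data.frame with columns \code{k} and \code{cost}; attribute
#'   \code{"elbow"} holds the \code{k} with maximal curvature.
#' @export
elbowCurve <- function(similarity, kRange = 2:12) {
  kRange <- sort(unique(as.integer(kRange)))
  cost <- vapply(kRange, function(k)
    clusterPatterns(similarity, k)$cost, 0)
  out <- data.frame(k = kRange, cost = cost)
  if (length(kRange) >= 3L) {
    curv <- diff(diff(cost))   # positive where the curve flattens
    attr(out, "elbow") <- kRange[which.max(curv) + 1L]
  }
  out
}

#' Mean pattern of a cluster
#'
#' Reconstructs the smooth field corresponding to the mean of the member
#' genes' coefficient vectors on a grid over the common domain.
#'
#' @param k matrix of member coefficient vectors (rows = genes).
#' @param basis the [SwarmBasis].
#' @param grid data.frame of \code{t_tilde}, \code{p_tilde} points;
#'   defaults to [domainGrid()].
#' @return the grid with a \code{value} column appended.
#' @export
meanPattern <- function(k, basis, grid = domainGrid(basis)) {
  k <- as.matrix(k)
  if (nrow(k) == 0L) stop("empty cluster")
  grid$value <- reconstructField(colMeans(k), basis, grid)
  grid
}

#' Metric multidimensional scaling of pattern similarities
#'
#' Embeds genes (and, when scored through the same spectral pipeline,
#' phenotype properties) in 2-D from their cosine distances
#' \eqn{1 - d_{np}} by SMACOF stress majorisation, initialised from
#' classical scaling. The run is deterministic for a given input.
#'
#' @param similarity cosine similarity matrix.
#' @param ndim embedding dimension (default 2).
#' @param maxit,tol majorisation iteration controls.
#' @return list with \code{coords} (n x ndim matrix) and \code{stress}
#'   (normalised Kruskal stress-1).
#' @export
mdsEmbed <- function(similarity, ndim = 2L, maxit = 300L, tol = 1e-10) {
  Delta <- as.matrix(1 - similarity)
  n <- nrow(Delta)
  X <- cmdscale(Delta, k = ndim)
  if (ncol(X) < ndim)
    X <- cbind(X, matrix(0, n, ndim - ncol(X)))
  denom <- sum(Delta^2) / 2
  stress <- function(X) {
    d <- as.matrix(dist(X))
    sqrt(sum((Delta[upper.tri(Delta)] - d[upper.tri(d)])^2) /
           sum(Delta[upper.tri(Delta)]^2))
  }
  s0 <- stress(X)
  for (it in seq_len(maxit)) {
    d <- as.matrix(dist(X))
    ratio <- ifelse(d > 0, Delta / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    s1 <- stress(X)
    if (abs(s0 - s1) < tol) break
    s0 <- s1
  }
  rownames(X) <- rownames(similarity)
  list(coords = X, stress = stress(X))
}

#' Gene-function composition of a phenotype's MDS neighbourhood
#'
#' Finds the \code{n} genes nearest a phenotype's point in the embedding and
#' tabulates their function categories. Categories carrying fewer than
#' \code{minCategory} genes in the whole table are merged into
#' \code{"other"}; ties at the n-th distance are broken by gene id order.
#'
#' @param coords gene embedding coordinates (rows named by gene).
#' @param point numeric vector, the phenotype's coordinates.
#' @param functionTable data.frame with columns \code{gene} and
#'   \code{category}.
#' @param n neighbourhood size (default 50).
#' @param minCategory categories smaller than this are merged into
#'   \code{"other"} (default 10).
#' @return named integer vector of category counts, summing to \code{n}.
#' @export
neighborFunctions <- function(coords, point, functionTable, n = 50L,
                              minCategory = 10L) {
  coords <- as.matrix(coords)
  if (n > nrow(coords)) stop("'n' exceeds the number of genes")
  ft <- as.data.frame(functionTable)
  stopifnot(all(c("gene", "category") %in% names(ft)))
  cat <- setNames(as.character(ft$category), as.character(ft$gene))
  tab <- table(cat)
  small <- names(tab)[tab < minCategory]
  cat[cat %in% small] <- "other"
  d <- sqrt(colSums((t(coords) - point)^2))
  ord <- order(d, rownames(coords))
  near <- rownames(coords)[ord[seq_len(n)]]
  cats <- cat[near]
  cats[is.na(cats)] <- "other"
  counts <- table(cats)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
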