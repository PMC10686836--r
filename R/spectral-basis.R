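# Graded monomial exponent table: 1, t, p, t^2, tp, p^2, ...
gradedMonomials <- function(n) {
  out <- matrix(0L, nrow = 0L, ncol = 2L)
  d <- 0L
  while (nrow(out) < n) {
    out <- rbind(out, cbind(d:0L, 0L:d))
    d <- d + 1L
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("t", "p")
  out
}

evalMonomials <- function(exponents, t, p) {
  out <- matrix(0, length(t), nrow(exponents))
  for (i in seq_len(nrow(exponents)))
    out[, i] <- t^exponents[i, 1L] * p^exponents[i, 2L]
  out
}

#' Quadrature for the weighted swarm-domain inner product
#'
#' Builds a tensor Gauss-Legendre rule for
#' \deqn{\langle f, g\rangle = \int_0^T \mathrm{d}\tilde t
#'   \int_0^{e^{\tilde t}} \mathrm{d}\tilde p\; e^{-\tilde t}\, f g:}
#' Gauss-Legendre nodes on \eqn{[0, T]} in \eqn{\tilde t}, and for each
#' \eqn{\tilde t} node the inner integral over
#' \eqn{\tilde p \in [0, e^{\tilde t}]} is mapped from a reference
#' Gauss-Legendre rule on \eqn{[0, 1]}. The Jacobian \eqn{e^{\tilde t}} of
#' that map cancels the \eqn{e^{-\tilde t}} weight exactly, so the combined
#' weights are the plain tensor products and \eqn{\langle 1, 1\rangle = T}
#' holds to machine precision.
#'
#' @param Tmax domain extent \eqn{T > 0}.
#' @param nNodes integer pair: node counts along \eqn{\tilde t} and
#'   \eqn{\tilde p} (default 64 x 64).
#'
#' @return list with \code{nodes} (two-column matrix), \code{weights}, and
#'   an \code{ip(fvals, gvals)} convenience closure.
#' @export
buildInnerProduct <- function(Tmax, nNodes = c(64L, 64L)) {
  if (length(Tmax) != 1L || !is.finite(Tmax) || Tmax <= 0)
    stop("'Tmax' must be a single positive number")
  nNodes <- rep_len(as.integer(nNodes), 2L)
  gt <- pracma::gaussLegendre(nNodes[1L], 0, Tmax)
  gu <- pracma::gaussLegendre(nNodes[2L], 0, 1)
  tt <- rep(gt$x, each = nNodes[2L])
  pp <- rep(gu$x, times = nNodes[1L]) * exp(tt)
  ww <- rep(gt$w, each = nNodes[2L]) * rep(gu$w, times = nNodes[1L])
  list(
    nodes = cbind(t = tt, p = pp),
    weights = ww,
    nodeCounts = nNodes,
    Tmax = Tmax,
    ip = function(f, g) sum(ww * f * g)
  )
}

#' Build the orthonormal polynomial basis on the swarm domain
#'
#' Applies Gram-Schmidt orthogonalisation (classical, with a second
#' re-orthogonalisation pass for numerical stability) to the graded monomial
#' sequence \eqn{1, \tilde t, \tilde p, \tilde t^2, \tilde t\tilde p,
#' \tilde p^2, \dots} under the weighted inner product of
#' [buildInnerProduct()]. Basis functions are normalised to unit norm, which
#' fixes the constant function at \eqn{P_0 = 1/\sqrt{T}} and makes
#' coefficients comparable across basis functions.
#'
#' @param Tmax domain extent \eqn{T}.
#' @param M highest basis index (default 5, i.e. six functions).
#' @param nNodes quadrature node counts, see [buildInnerProduct()].
#'
#' @return a [SwarmBasis].
#' @examples
#' b <- swarmBasis(Tmax = 2)
#' constantValue(b)            # 1 / sqrt(2)
#' @export
swarmBasis <- function(Tmax, M = 5L, nNodes = c(64L, 64L)) {
  M <- as.integer(M)
  if (M < 0L) stop("'M' must be non-negative")
  ip <- buildInnerProduct(Tmax, nNodes)
  exps <- gradedMonomials(M + 1L)
  V <- evalMonomials(exps, ip$nodes[, "t"], ip$nodes[, "p"])
  # monomial Gram matrix under the weighted inner product
  G <- crossprod(V, ip$weights * V)
  nm <- M + 1L
  C <- matrix(0, nm, nm)
  monoName <- function(i) {
    e <- exps[i, ]
    if (all(e == 0L)) return("1")
    paste0(c(if (e[1L] > 0L) paste0("t^", e[1L]),
             if (e[2L] > 0L) paste0("p^", e[2L])), collapse = " * ")
  }
  for (m in seq_len(nm)) {
    v <- numeric(nm); v[m] <- 1
    for (pass in 1:2) {
      if (m > 1L) for (j in seq_len(m - 1L)) {
        v <- v - drop(C[j, ] %*% G %*% v) * C[j, ]
      }
    }
    nrm2 <- drop(v %*% G %*% v)
    if (nrm2 <= 1e-12 * G[m, m])
      stop("numerical rank deficiency at monomial ", monoName(m))
    C[m, ] <- v / sqrt(nrm2)
  }
  new("SwarmBasis", Tmax = Tmax, M = M, exponents = exps,
      coefficients = C, nodes = ip$nodes, weights = ip$weights,
      nodeCounts = ip$nodeCounts)
}

#' Gram matrix of a basis (orthonormality check)
#'
#' @param basis a [SwarmBasis].
#' @param nNodes optional finer quadrature for an independent check.
#' @return the \eqn{(M+1)\times(M+1)} matrix of pairwise inner products.
#' @export
basisGram <- function(basis, nNodes = NULL) {
  if (is.null(nNodes)) {
    nodes <- basis@nodes; w <- basis@weights
  } else {
    ipq <- buildInnerProduct(basis@Tmax, nNodes)
    nodes <- ipq$nodes; w <- ipq$weights
  }
  V <- evalMonomials(basis@exponents, nodes[, "t"], nodes[, "p"])
  P <- V %*% t(basis@coefficients)
  crossprod(P, w * P)
}

#' Evaluate the basis design matrix at sample coordinates
#'
#' Entry \eqn{(l, m)} is \eqn{P_m(\tilde t_l, \tilde p_l)}. Coordinates must
#' lie inside the domain (use [nondimensionalize()] and its
#' \code{in_domain} flag first).
#'
#' @param basis a [SwarmBasis].
#' @param coords data.frame (or matrix) with columns \code{t_tilde} and
#'   \code{p_tilde}; if an \code{in_domain} column is present it must be all
#'   \code{TRUE}.
#' @param check reject out-of-domain coordinates (default \code{TRUE}).
#' @return numeric matrix, one row per coordinate, \code{M + 1} columns.
#' @export
evaluateDesign <- function(basis, coords, check = TRUE) {
  coords <- as.data.frame(coords)
  tt <- coords$t_tilde
  pp <- coords$p_tilde
  if (check) {
    eps <- 1e-9 * max(1, basis@Tmax)
    ok <- tt >= -eps & tt <= basis@Tmax + eps & pp >= -eps &
      pp <= exp(tt) * (1 + 1e-9) + eps
    if (!all(ok))
      stop(sum(!ok), " coordinate(s) outside the domain")
  }
  V <- evalMonomials(basis@exponents, tt, pp)
  X <- V %*% t(basis@coefficients)
  colnames(X) <- paste0("P", 0:basis@M)
  X
}

# least squares with min-norm fallback for rank-deficient designs
lsSolve <- function(X, Y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient design; returning minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    Ci <- sv$v[, pos, drop = FALSE] %*%
      ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE])) %*% Y
    return(Ci)
  }
  qr.coef(qrX, Y)
}

#' Fit spectral coefficients by least squares
#'
#' Solves \eqn{g = [P_0\; P_1 \cdots P_M]\, c} by ordinary least squares for
#' one or many genes. \code{fitSpectral} fits one replicate's design;
#' \code{fitSpectralStacked} vertically stacks the per-replicate systems so
#' a single coefficient vector is fitted per gene across replicates.
#'
#' @param values numeric vector (one gene) or gene-by-sample matrix; columns
#'   must align with the rows of \code{design}.
#' @param design design matrix from [evaluateDesign()].
#' @return coefficient vector, or gene-by-basis matrix.
#' @export
fitSpectral <- function(values, design) {
  single <- is.null(dim(values))
  Y <- if (single) cbind(values) else t(values)
  if (nrow(Y) != nrow(design))
    stop("number of samples does not match design rows")
  if (nrow(design) < ncol(design))
    warning("fewer samples than basis functions; fit is underdetermined")
  Ci <- lsSolve(design, Y)
  if (single) drop(Ci) else {
    out <- t(Ci)
    dimnames(out) <- list(rownames(values), colnames(design))
    out
  }
}

#' @rdname fitSpectral
#' @param valuesList list of per-replicate gene-by-sample matrices (same
#'   gene order in each).
#' @param designList list of per-replicate design matrices.
#' @export
fitSpectralStacked <- function(valuesList, designList) {
  stopifnot(length(valuesList) == length(designList))
  X <- do.call(rbind, designList)
  Y <- do.call(cbind, valuesList)
  fitSpectral(Y, X)
}

#' Reconstruct a smooth field from spectral coefficients
#'
#' Evaluates \eqn{\bar g(\tilde t, \tilde p) = \sum_m \bar c_m
#' P_m(\tilde t, \tilde p)} on a coordinate grid.
#'
#' @param coefficients numeric vector of length \code{M + 1} (or gene-by-basis
#'   matrix).
#' @param basis a [SwarmBasis].
#' @param coords data.frame with columns \code{t_tilde}, \code{p_tilde}.
#' @return numeric vector (or gene-by-point matrix) of field values.
#' @export
reconstructField <- function(coefficients, basis, coords) {
  X <- evaluateDesign(basis, coords, check = FALSE)
  if (is.null(dim(coefficients))) drop(X %*% coefficients)
  else coefficients %*% t(X)
}

#' Regular evaluation grid over the swarm domain
#'
#' @param basis a [SwarmBasis] (or anything with a \code{Tmax} slot).
#' @param nt,np grid resolution in time and radius.
#' @return data.frame of in-domain \code{t_tilde}, \code{p_tilde} points.
#' @export
domainGrid <- function(basis, nt = 50L, np = 50L) {
  tt <- seq(0, basis@Tmax, length.out = nt)
  out <- do.call(rbind, lapply(tt, function(t1) {
    data.frame(t_tilde = t1, p_tilde = seq(0, exp(t1), length.out = np))
  }))
  out
}

#' Serialise / restore a basis
#'
#' The monomial coefficient table, domain extent and node counts fully
#' determine the basis, so fits are reproducible across runs to full
#' numeric precision.
#'
#' @param basis a [SwarmBasis].
#' @param path file to write (JSON).
#' @export
writeSwarmBasis <- function(basis, path) {
  x <- list(Tmax = basis@Tmax, M = basis@M,
            nodeCounts = basis@nodeCounts,
            coefficients = as.numeric(basis@coefficients))  # column-major
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSwarmBasis
#' @export
readSwarmBasis <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- swarmBasis(x$Tmax, M = x$M, nNodes = x$nodeCounts)
  # trust the stored coefficient table over re-derivation
  b@coefficients <- matrix(x$coefficients, nrow = x$M + 1L)
  b
}
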