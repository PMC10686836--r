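#' Simulate exponential boundary observations
#'
#' Boundary radii \eqn{b(t) = b_0 e^{t/\tau}} observed at regular times,
#' optionally with zero-mean Gaussian measurement noise (radii are kept
#' strictly positive). With \eqn{\tau = 6/\log 60 \approx 1.47} h, a
#' 1 mm colony reaches 60 mm diameter within about 6 h, the regime the
#' generator emulates by default.
#'
#' @param tau growth timescale in hours (> 0).
#' @param b0 named numeric, initial radius (mm) per replicate (> 0).
#' @param tEnd duration in hours.
#' @param by observation interval in hours (default 1/3, i.e. 20 min).
#' @param obsNoise observation noise SD in mm (default 0).
#' @param seed integer seed.
#' @return data.frame with columns \code{replicate}, \code{time},
#'   \code{radius}.
#' @export
simBoundary <- function(tau, b0, tEnd, by = 1 / 3, obsNoise = 0,
                        seed = 1L) {
  if (tau <= 0) stop("'tau' must be positive")
  if (any(b0 <= 0)) stop("all 'b0' must be positive")
  if (is.null(names(b0))) names(b0) <- paste0("r", seq_along(b0))
  set.seed(seed)
  out <- do.call(rbind, lapply(names(b0), function(k) {
    tt <- seq(0, tEnd, by = by)
    r <- b0[[k]] * exp(tt / tau)
    if (obsNoise > 0)
      r <- pmax(r + rnorm(length(tt), 0, obsNoise), .Machine$double.eps)
    data.frame(replicate = k, time = tt, radius = r)
  }))
  rownames(out) <- NULL
  out
}

# Radial sampling positions inside a boundary: innermost at 1.5 mm,
# regular spacing of at least 1 mm, at most maxPositions positions.
samplingPositions <- function(boundary, innermost = 1.5, minSpacing = 1,
                              maxPositions = 9L) {
  if (boundary < innermost) return(numeric())
  n <- min(maxPositions, floor((boundary - innermost) / minSpacing) + 1L)
  spacing <- if (n >= maxPositions && n > 1L)
    (boundary - innermost) / (n - 1L) else minSpacing
  innermost + (seq_len(n) - 1L) * spacing
}

#' Simulate the space-time sampling grid
#'
#' Emulates the robotic sampling protocol: sets of radial positions are
#' sampled at regular intervals during expansion, with the innermost
#' position 1.5 mm from the inoculation point, a spacing of at least 1 mm,
#' and at most 9 positions per sweep; all positions lie inside the colony
#' boundary at their sampling time.
#'
#' @param tau,b0 boundary parameters as in [simBoundary()].
#' @param tEnd sampling duration in hours.
#' @param interval sweep interval in hours (default 1/3 h = 20 min;
#'   the protocol range is 15-20 min).
#' @param maxPositions at most this many positions per sweep (default 9).
#' @param innermost innermost radial position in mm (default 1.5).
#' @param minSpacing minimum spacing in mm (default 1).
#' @return annotation data.frame with columns \code{sample_id},
#'   \code{replicate}, \code{time}, \code{position}, \code{boundary}.
#' @export
simSamplingGrid <- function(tau, b0, tEnd, interval = 1 / 3,
                            maxPositions = 9L, innermost = 1.5,
                            minSpacing = 1) {
  if (interval <= 0) stop("'interval' must be positive")
  if (maxPositions > 9L)
    stop("'maxPositions' must be at most 9")
  if (is.null(names(b0))) names(b0) <- paste0("r", seq_along(b0))
  rows <- list()
  for (k in names(b0)) {
    for (tt in seq(0, tEnd, by = interval)) {
      bnd <- b0[[k]] * exp(tt / tau)
      pos <- samplingPositions(bnd, innermost, minSpacing, maxPositions)
      if (length(pos))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = k, time = tt, position = pos, boundary = bnd)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(sample_id = character(), replicate = character(),
                      time = numeric(), position = numeric(),
                      boundary = numeric()))
  out <- do.call(rbind, rows)
  out <- data.frame(sample_id = sprintf("s%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Simulate expression fields from known spectral coefficients
#'
#' Each gene's field is the linear combination of the basis functions given
#' by its ground-truth coefficient row, evaluated at the scaled sample
#' coordinates, plus optional Gaussian noise on the log2 scale. With zero
#' noise the spectral fit recovers the coefficients exactly (round-trip
#' identity).
#'
#' @param coefficients gene-by-basis matrix of true coefficients.
#' @param basis a [SwarmBasis].
#' @param coords data.frame with in-domain \code{t_tilde}, \code{p_tilde}.
#' @param noiseSd Gaussian noise SD in log2 units (default 0).
#' @param seed integer seed.
#' @return gene-by-sample matrix of log2 expression values.
#' @export
simExpressionField <- function(coefficients, basis, coords, noiseSd = 0,
                               seed = 1L) {
  if (noiseSd < 0) stop("'noiseSd' must be non-negative")
  X <- evaluateDesign(basis, coords)      # rejects out-of-domain points
  coefficients <- as.matrix(coefficients)
  if (ncol(coefficients) != ncol(X))
    stop("coefficient columns must match the basis size")
  vals <- coefficients %*% t(X)
  if (noiseSd > 0) {
    set.seed(seed)
    vals <- vals + matrix(rnorm(length(vals), 0, noiseSd), nrow(vals))
  }
  rownames(vals) <- rownames(coefficients)
  colnames(vals) <- rownames(coords)
  vals
}

#' Simulate an overdispersed count matrix
#'
#' Negative-binomial counts with gene-level means proportional to
#' \eqn{2^{\mathrm{log2\,expression}}}, scaled within each sample so the
#' expected column total equals the library size; dispersion 0 reduces to
#' Poisson. This is the standard overdispersed RNA-seq emulation the TMM
#' normalisation stage assumes.
#'
#' @param log2expr gene-by-sample matrix of log2 expression values.
#' @param librarySizes per-sample expected total counts (non-negative).
#' @param dispersion negative-binomial dispersion (variance =
#'   \eqn{\mu + \phi\mu^2}); 0 gives Poisson.
#' @param seed integer seed.
#' @return integer gene-by-sample count matrix.
#' @export
simCounts <- function(log2expr, librarySizes, dispersion = 0.05,
                      seed = 1L) {
  log2expr <- as.matrix(log2expr)
  if (!all(is.finite(log2expr))) stop("expression values must be finite")
  if (any(librarySizes < 0)) stop("library sizes must be non-negative")
  if (dispersion < 0) stop("'dispersion' must be non-negative")
  librarySizes <- rep_len(librarySizes, ncol(log2expr))
  lin <- 2^log2expr
  prop <- sweep(lin, 2L, colSums(lin), "/")
  mu <- sweep(prop, 2L, librarySizes, "*")
  set.seed(seed)
  counts <- if (dispersion == 0) {
    matrix(rpois(length(mu), mu), nrow(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow(mu))
  }
  dimnames(counts) <- dimnames(log2expr)
  counts
}

#' Simulate per-frame cell tables
#'
#' Constructed cell configurations for the phenotype metrics, built so the
#' expected detections are provable rather than probabilistic:
#' \describe{
#'   \item{\code{isotropic}}{cells uniform in the field with orientations
#'     uniform on \eqn{[0, \pi)} and motile speeds.}
#'   \item{\code{raft}}{half the cells form a compact co-moving group
#'     (common orientation within \eqn{\pm 2^\circ}, speeds 15-25 um/s)
#'     well separated from an isotropic background, so raft members'
#'     local rafting ratios exceed 0.9.}
#'   \item{\code{non_motile_cluster}}{12 slow cells (2 um/s) in a chain
#'     with 1.5 um spacing -- one detectable cluster -- plus motile
#'     background cells.}
#'   \item{\code{mixed}}{raft, non-motile cluster and isotropic background
#'     in separate regions of the field.}
#' }
#'
#' @param scenario one of \code{"isotropic"}, \code{"raft"},
#'   \code{"non_motile_cluster"}, \code{"mixed"}.
#' @param nCells total cell count (>= 0).
#' @param fieldSize field-of-view edge length in um (default 400).
#' @param seed integer seed.
#' @return cell table data.frame with columns \code{frame}, \code{x},
#'   \code{y}, \code{orientation}, \code{speed}, \code{area}; raft /
#'   cluster member row indices are attached as attributes \code{"raft"} /
#'   \code{"cluster"}.
#' @export
simCellTable <- function(scenario = c("isotropic", "raft",
                                      "non_motile_cluster", "mixed"),
                         nCells = 100L, fieldSize = 400, seed = 1L) {
  scenario <- match.arg(scenario)
  if (nCells < 0) stop("'nCells' must be non-negative")
  set.seed(seed)
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      orientation = numeric(), speed = numeric(),
                      area = numeric())
  if (nCells == 0L) return(empty)
  isoCells <- function(n, xr, yr) {
    data.frame(frame = 1L,
               x = runif(n, xr[1L], xr[2L]), y = runif(n, yr[1L], yr[2L]),
               orientation = runif(n, 0, pi), speed = runif(n, 10, 30),
               area = runif(n, 2, 5))
  }
  raftCells <- function(n, cx, cy) {
    ang <- pi / 3
    data.frame(frame = 1L,
               x = cx + runif(n, -10, 10), y = cy + runif(n, -10, 10),
               orientation = (ang + runif(n, -2, 2) * pi / 180) %% pi,
               speed = runif(n, 15, 25), area = runif(n, 2, 5))
  }
  chainCells <- function(n, cx, cy) {
    data.frame(frame = 1L,
               x = cx + (seq_len(n) - 1L) * 1.5, y = cy,
               orientation = 0, speed = 2, area = runif(n, 2, 5))
  }
  out <- switch(scenario,
    isotropic = isoCells(nCells, c(0, fieldSize), c(0, fieldSize)),
    raft = {
      nr <- max(2L, ceiling(nCells / 2))
      nb <- nCells - nr
      raft <- raftCells(nr, fieldSize * 0.15, fieldSize * 0.15)
      bg <- if (nb > 0)
        isoCells(nb, c(fieldSize * 0.5, fieldSize),
                 c(fieldSize * 0.5, fieldSize)) else empty
      r <- rbind(raft, bg)
      attr(r, "raft") <- seq_len(nr)
      r
    },
    non_motile_cluster = {
      nc <- min(12L, max(10L, nCells))
      nb <- max(0L, nCells - nc)
      ch <- chainCells(nc, fieldSize * 0.1, fieldSize * 0.1)
      bg <- if (nb > 0)
        isoCells(nb, c(fieldSize * 0.5, fieldSize),
                 c(fieldSize * 0.5, fieldSize)) else empty
      r <- rbind(ch, bg)
      attr(r, "cluster") <- seq_len(nc)
      r
    },
    mixed = {
      nr <- max(2L, floor(nCells / 3))
      nc <- 12L
      nb <- max(0L, nCells - nr - nc)
      raft <- raftCells(nr, fieldSize * 0.15, fieldSize * 0.15)
      ch <- chainCells(nc, fieldSize * 0.15, fieldSize * 0.85)
      bg <- if (nb > 0)
        isoCells(nb, c(fieldSize * 0.6, fieldSize),
                 c(fieldSize * 0.6, fieldSize)) else empty
      r <- rbind(raft, ch, bg)
      attr(r, "raft") <- seq_len(nr)
      attr(r, "cluster") <- nr + seq_len(nc)
      r
    })
  rownames(out) <- NULL
  out
}

#' Simulate secrete-then-consume metabolite series
#'
#' Concentration at each position rises after the swarm front passes,
#' peaks, and decays as the compound is consumed. The shape is the product
#' of a logistic rise at front arrival and an equally steep logistic fall,
#' which by symmetry peaks exactly at arrival + \code{consumptionDelay};
#' peak times are therefore ordered with position and shifted by
#' spacing / front speed between positions.
#'
#' @param positions sorted radial positions in mm.
#' @param frontSpeed front propagation speed in mm/h (used with
#'   \code{t0} to set arrival times), or give \code{arrivalTimes}
#'   directly.
#' @param arrivalTimes optional explicit front-passage time per position.
#' @param times sampling times in hours.
#' @param amplitude peak scale of the secretion pulse (concentration
#'   units); must be non-negative, 0 gives a flat series.
#' @param consumptionDelay hours from front passage to the concentration
#'   peak (default 2).
#' @param steepness logistic steepness in 1/h (default 2).
#' @param noise Gaussian noise SD on concentrations (default 0; values are
#'   truncated at 0).
#' @param nReplicates replicates per timepoint (default 4).
#' @param t0 front-passage time at position 0 (default 0.5 h).
#' @param seed integer seed.
#' @return long-format data.frame (\code{compound}, \code{position},
#'   \code{time}, \code{replicate}, \code{concentration}); configured peak
#'   times attached as attribute \code{"peakTimes"}.
#' @export
simMetaboliteSeries <- function(positions, frontSpeed = 5,
                                arrivalTimes = NULL,
                                times = seq(0, 24, by = 2),
                                amplitude = 1, consumptionDelay = 2,
                                steepness = 2, noise = 0,
                                nReplicates = 4L, t0 = 0.5, seed = 1L) {
  if (is.unsorted(positions)) stop("'positions' must be sorted ascending")
  if (amplitude < 0 || steepness <= 0 || consumptionDelay <= 0 ||
      (is.null(arrivalTimes) && frontSpeed <= 0))
    stop("rates must be positive and 'amplitude' non-negative")
  if (is.null(arrivalTimes)) arrivalTimes <- t0 + positions / frontSpeed
  stopifnot(length(arrivalTimes) == length(positions))
  peaks <- arrivalTimes + consumptionDelay
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_along(positions), function(i) {
    ta <- arrivalTimes[i]
    shape <- stats::plogis(steepness * (times - ta)) *
      stats::plogis(steepness * (ta + 2 * consumptionDelay - times))
    do.call(rbind, lapply(seq_len(nReplicates), function(rep) {
      conc <- amplitude * shape
      if (noise > 0)
        conc <- pmax(0, conc + rnorm(length(conc), 0, noise))
      data.frame(compound = "pyruvate", position = positions[i],
                 time = times, replicate = rep, concentration = conc)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "peakTimes") <- setNames(peaks, positions)
  out
}

#' Simulate a complete synthetic swarm study
#'
#' Generates everything the transcriptome pipeline consumes, with known
#' ground truth: a shared exponential domain over three replicates
#' (defaults \eqn{\tau = 6/\log 60} h, initial radii 0.5/0.55/0.6 mm over
#' 6 h, matching a colony growing from 1 mm to 60 mm diameter in ~6 h),
#' the sampling grid, the domain basis, ground-truth coefficients for a
#' cohort of flat and patterned genes (patterned genes drawn from
#' \code{nFamilies} well-separated coefficient-direction families), and
#' the resulting noisy log2 expression fields.
#'
#' @param nFlat,nPatterned cohort composition (defaults 500 flat, 100
#'   patterned).
#' @param nFamilies number of planted pattern families (default 6).
#' @param tau,b0,tEnd domain parameters.
#' @param M basis size index (default 5).
#' @param nNodes quadrature nodes (default 48 x 48 for simulation speed).
#' @param noiseSd expression noise SD in log2 units (default 0.2).
#' @param amplitude pattern-energy scale of patterned genes (default 2).
#' @param seed integer seed.
#' @return list with \code{domain} ([SwarmDomain]), \code{basis},
#'   \code{annotations} (with scaled coordinates), \code{expression}
#'   (gene-by-sample log2 matrix over in-domain samples),
#'   \code{coefficients} (ground truth), \code{patterned} (logical),
#'   \code{family} (integer or NA), \code{boundaryObs}.
#' @export
simSwarmStudy <- function(nFlat = 500L, nPatterned = 100L, nFamilies = 6L,
                          tau = 6 / log(60), b0 = c(r1 = 0.5, r2 = 0.55,
                                                    r3 = 0.6),
                          tEnd = 6, M = 5L, nNodes = c(48L, 48L),
                          noiseSd = 0.2, amplitude = 2, seed = 1L) {
  set.seed(seed)
  boundaryObs <- simBoundary(tau, b0, tEnd, seed = seed)
  domain <- fitBoundary(boundaryObs)
  ann <- simSamplingGrid(tau, b0, tEnd)
  ann <- nondimensionalize(ann, domain)
  ann <- ann[ann$in_domain, , drop = FALSE]
  basis <- swarmBasis(domain@Tmax, M = M, nNodes = nNodes)

  nGenes <- nFlat + nPatterned
  geneIds <- sprintf("g%04d", seq_len(nGenes))
  mu <- runif(nGenes, 4, 12)
  p0 <- constantValue(basis)
  coefs <- matrix(0, nGenes, M + 1L,
                  dimnames = list(geneIds, paste0("P", 0:M)))
  coefs[, 1L] <- mu / p0
  patterned <- c(rep(FALSE, nFlat), rep(TRUE, nPatterned))
  family <- rep(NA_integer_, nGenes)
  # family templates: the M coordinate axes plus mixed directions,
  # mutually well separated in cosine similarity
  templates <- diag(M)
  extra <- nFamilies - M
  if (extra > 0) {
    mixed <- matrix(1, extra, M)
    if (extra > 1)
      for (i in 2:extra) mixed[i, seq_len(i - 1L)] <- -1
    templates <- rbind(templates, mixed / sqrt(rowSums(mixed^2)))
  }
  templates <- templates[seq_len(nFamilies), , drop = FALSE]
  if (nPatterned > 0) {
    fam <- rep(seq_len(nFamilies), length.out = nPatterned)
    family[nFlat + seq_len(nPatterned)] <- fam
    amps <- runif(nPatterned, 0.75, 1.25) * amplitude
    wob <- matrix(rnorm(nPatterned * M, 0, 0.05), nPatterned)
    dirs <- templates[fam, , drop = FALSE] + wob
    dirs <- dirs / sqrt(rowSums(dirs^2))
    coefs[nFlat + seq_len(nPatterned), -1L] <- amps * dirs
  }
  expr <- simExpressionField(coefs, basis,
                             ann[, c("t_tilde", "p_tilde")],
                             noiseSd = noiseSd, seed = seed + 1L)
  colnames(expr) <- ann$sample_id
  list(domain = domain, basis = basis, annotations = ann,
       expression = expr, coefficients = coefs, patterned = patterned,
       family = family, boundaryObs = boundaryObs)
}

#' Write / read synthetic study pieces
#'
#' Convenience TSV/YAML writers so generated inputs round-trip through the
#' same file formats the pipeline reads.
#'
#' @param x data.frame to write.
#' @param path output file.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) utils::read.delim(path, check.names = FALSE)

#' @rdname writeTSV
#' @param config named list of generator/pipeline parameters.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeTSV
#' @export
readConfig <- function(path) yaml::read_yaml(path)
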