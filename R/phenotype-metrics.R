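# Axial angle difference: orientations are head-tail symmetric (mod pi)
axialDiff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

checkCellTable <- function(cells) {
  cells <- as.data.frame(cells)
  need <- c("x", "y", "orientation", "speed")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(cells$speed < 0)) stop("speeds must be non-negative")
  if (is.null(cells$frame)) cells$frame <- 1L
  cells
}

#' Pair nematic order parameter
#'
#' Alignment of two axial (head-tail symmetric) cell orientations with
#' relative angle \eqn{\vartheta}:
#' \deqn{S(\vartheta) = 1.5\,\cos^2(\vartheta) - 0.5,}
#' so \eqn{S = 1} for parallel and \eqn{S = -0.5} for perpendicular cells;
#' the function is \eqn{\pi}-periodic.
#'
#' @param theta relative angle in radians (any real value).
#' @return value in \eqn{[-0.5, 1]}.
#' @export
pairNematicOrder <- function(theta) 1.5 * cos(theta)^2 - 0.5

#' Local nematic order per cell
#'
#' For each cell, the mean pair nematic order with every neighbour whose
#' centroid lies within \code{radius} (inclusive). Cells with no neighbour
#' get \code{NA} and are excluded from aggregation.
#'
#' @param cells cell table with columns \code{x}, \code{y},
#'   \code{orientation} (rad), \code{speed}; processed per \code{frame} if
#'   present.
#' @param radius neighbourhood radius in micrometres (default 10).
#' @return numeric vector, one value per cell (row order preserved).
#' @export
localNematicOrder <- function(cells, radius = 10) {
  if (radius <= 0) stop("'radius' must be positive")
  cells <- checkCellTable(cells)
  out <- rep(NA_real_, nrow(cells))
  for (f in split(seq_len(nrow(cells)), cells$frame)) {
    if (length(f) < 2L) next
    d <- as.matrix(dist(cells[f, c("x", "y")]))
    th <- cells$orientation[f]
    for (i in seq_along(f)) {
      nb <- which(d[i, ] <= radius & seq_along(f) != i)
      if (length(nb))
        out[f[i]] <- mean(pairNematicOrder(th[i] - th[nb]))
    }
  }
  out
}

#' Detect non-motile cell clusters
#'
#' Cells slower than \code{speedCutoff} (strictly) are linked by
#' single-linkage hierarchical clustering on centroid distance cut at
#' \code{linkCutoff}; only connected groups with at least \code{minSize}
#' members count as clusters.
#'
#' @param cells cell table (one frame, or processed per \code{frame}).
#' @param speedCutoff non-motile speed threshold, strict (default
#'   8 um/s).
#' @param linkCutoff single-linkage distance cut (default 2 um).
#' @param minSize minimum cluster size (default 10).
#' @return data.frame with columns \code{frame}, \code{cluster},
#'   \code{n_cells}; member row indices attached as attribute
#'   \code{"members"}.
#' @export
nonMotileClusters <- function(cells, speedCutoff = 8, linkCutoff = 2,
                              minSize = 10L) {
  if (speedCutoff <= 0 || linkCutoff <= 0) stop("cutoffs must be positive")
  cells <- checkCellTable(cells)
  res <- list(); members <- list()
  for (fr in unique(cells$frame)) {
    idx <- which(cells$frame == fr & cells$speed < speedCutoff)
    if (length(idx) == 0L) next
    lab <- if (length(idx) == 1L) 1L else
      cutree(hclust(dist(cells[idx, c("x", "y")]), method = "single"),
             h = linkCutoff)
    for (cl in unique(lab)) {
      m <- idx[lab == cl]
      if (length(m) >= minSize) {
        res[[length(res) + 1L]] <- data.frame(
          frame = fr, cluster = length(res) + 1L, n_cells = length(m))
        members[[length(members) + 1L]] <- m
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(frame = integer(), cluster = integer(),
               n_cells = integer())
  attr(out, "members") <- members
  out
}

#' Local rafting ratio per cell
#'
#' The neighbourhood of a cell is every other cell within \code{radius}
#' (inclusive). The rafting ratio is the number of motile neighbours
#' (speed of \code{motileSpeed} or more) sharing the cell's orientation up
#' to \code{angleTol}, divided by the total number of neighbours. Cells
#' with an empty neighbourhood get \code{NA}.
#'
#' @param cells cell table; processed per \code{frame} if present.
#' @param radius neighbourhood radius in micrometres (default 30).
#' @param motileSpeed motile threshold, inclusive (default 10 um/s).
#' @param angleTol axial orientation tolerance in degrees (default 15).
#' @return numeric vector in \eqn{[0, 1]} (or \code{NA}), one per cell.
#' @export
localRaftingRatio <- function(cells, radius = 30, motileSpeed = 10,
                              angleTol = 15) {
  cells <- checkCellTable(cells)
  tolRad <- angleTol * pi / 180
  out <- rep(NA_real_, nrow(cells))
  for (f in split(seq_len(nrow(cells)), cells$frame)) {
    if (length(f) < 2L) next
    d <- as.matrix(dist(cells[f, c("x", "y")]))
    th <- cells$orientation[f]
    sp <- cells$speed[f]
    for (i in seq_along(f)) {
      nb <- which(d[i, ] <= radius & seq_along(f) != i)
      if (length(nb) == 0L) next
      aligned <- sp[nb] >= motileSpeed &
        axialDiff(th[i], th[nb]) <= tolRad
      out[f[i]] <- sum(aligned) / length(nb)
    }
  }
  out
}

#' Biomass density fluctuations
#'
#' The field of view is split into square tiles (default 48 x 48 um;
#' partial edge tiles are dropped) and each tile's density is the fraction
#' of its area covered by cells. The per-frame value is the population
#' standard deviation of tile densities; the video value is the mean over
#' frames. Cell coverage is approximated by assigning each cell's area to
#' the tile containing its centroid, capped at full coverage.
#'
#' @param cells cell table with an \code{area} column (um^2), or a list of
#'   per-frame tile-coverage matrices (values in \eqn{[0, 1]}).
#' @param fieldSize numeric pair, field-of-view width and height in um
#'   (required for cell tables).
#' @param tile tile edge length in um (default 48).
#' @return scalar: mean over frames of the spatial SD of tile densities.
#' @export
densityFluctuations <- function(cells, fieldSize = NULL, tile = 48) {
  popSD <- function(x) sqrt(mean((x - mean(x))^2))
  if (is.list(cells) && !is.data.frame(cells)) {
    perFrame <- vapply(cells, function(m) popSD(as.numeric(m)), 0)
    return(mean(perFrame))
  }
  cells <- checkCellTable(cells)
  if (is.null(cells$area)) stop("cell table needs an 'area' column")
  if (is.null(fieldSize)) stop("'fieldSize' is required for cell tables")
  fieldSize <- rep_len(fieldSize, 2L)
  nx <- floor(fieldSize[1L] / tile)
  ny <- floor(fieldSize[2L] / tile)
  if (nx < 1L || ny < 1L) stop("field of view smaller than one tile")
  frames <- unique(cells$frame)
  perFrame <- vapply(frames, function(fr) {
    d <- cells[cells$frame == fr, ]
    cov <- matrix(0, ny, nx)
    ix <- floor(d$x / tile) + 1L
    iy <- floor(d$y / tile) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    for (j in which(ok))
      cov[iy[j], ix[j]] <- cov[iy[j], ix[j]] + d$area[j] / tile^2
    cov[cov > 1] <- 1
    popSD(as.numeric(cov))
  }, 0)
  if (length(perFrame) == 0L) return(0)
  mean(perFrame)
}

#' Per-video summary properties
#'
#' Computes, per frame, the fraction of non-motile cells (speed strictly
#' below \code{nonMotileCutoff}), the median cell speed, the median cell
#' area, and the median local biomass density (fraction of a circle of
#' \code{biomassRadius} around each centroid covered by cells); per-cell
#' properties are aggregated as the median across the field of view and
#' then the mean across frames.
#'
#' @param cells cell table for one video (all frames).
#' @param nonMotileCutoff strict non-motile speed threshold (default 8).
#' @param biomassRadius radius of the local-density circle in um
#'   (default 30; the area estimate assigns each cell's area to its
#'   centroid).
#' @return named numeric vector: \code{non_motile_fraction},
#'   \code{mean_speed}, \code{mean_area}, \code{biomass_density}.
#' @export
simpleProperties <- function(cells, nonMotileCutoff = 8,
                             biomassRadius = 30) {
  cells <- checkCellTable(cells)
  hasArea <- !is.null(cells$area)
  frames <- unique(cells$frame)
  per <- lapply(frames, function(fr) {
    d <- cells[cells$frame == fr, ]
    if (nrow(d) == 0L) return(NULL)
    biomass <- NA_real_
    if (hasArea) {
      dd <- as.matrix(dist(d[, c("x", "y")]))
      circ <- pi * biomassRadius^2
      biomass <- median(vapply(seq_len(nrow(d)), function(i) {
        min(1, sum(d$area[dd[i, ] <= biomassRadius]) / circ)
      }, 0))
    }
    c(non_motile_fraction = mean(d$speed < nonMotileCutoff),
      mean_speed = median(d$speed),
      mean_area = if (hasArea) median(d$area) else NA_real_,
      biomass_density = biomass)
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (length(per) == 0L) stop("no non-empty frames")
  colMeans(do.call(rbind, per))
}

#' Phenotype kymograph
#'
#' Arranges one scalar per video (one property) into the same
#' (time, position) tile grid as the gene-expression kymographs, so the
#' property can be pushed through the identical spectral scoring pipeline
#' as the genes.
#'
#' @param values one scalar per video.
#' @param annotations annotations for the videos (columns \code{time},
#'   \code{position}).
#' @param property property name recorded on the result.
#' @return the [assembleKymograph()] data.frame with a \code{property}
#'   attribute.
#' @export
phenotypeKymograph <- function(values, annotations, property = "property") {
  out <- assembleKymograph(values, annotations)
  attr(out, "property") <- property
  out
}
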