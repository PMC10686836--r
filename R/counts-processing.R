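#' Filter lowly detected genes
#'
#' Keeps every gene with at least \code{minSamples} samples having a read
#' count of at least \code{minReads} (defaults: 10 reads in 2 samples).
#' Gene order is preserved; the operation is idempotent.
#'
#' @param counts gene-by-sample matrix of non-negative integer counts with
#'   unique row and column names.
#' @param minReads,minSamples detection thresholds.
#' @return the filtered count matrix.
#' @export
filterGenes <- function(counts, minReads = 10L, minSamples = 2L) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (minReads < 0 || minSamples < 0) stop("thresholds must be non-negative")
  keep <- rowSums(counts >= minReads) >= minSamples
  counts[keep, , drop = FALSE]
}

#' Filter shallow samples
#'
#' Removes samples whose total read count over the (already gene-filtered)
#' matrix is below \code{minTotal}; a total of exactly \code{minTotal} is
#' kept. Apply after [filterGenes()] so totals are over retained genes.
#'
#' @param counts gene-by-sample count matrix.
#' @param minTotal minimum library size (default \code{1e6}).
#' @return the filtered count matrix.
#' @export
filterSamples <- function(counts, minTotal = 1e6) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  keep <- colSums(counts) >= minTotal
  if (!any(keep))
    stop("all samples removed by the library-size filter")
  counts[, keep, drop = FALSE]
}

#' Trimmed mean of M-values (TMM) normalisation factors
#'
#' Between-sample scaling factors from the trimmed mean of log expression
#' ratios against a reference library: the reference is the sample whose
#' upper-quartile count fraction is closest to the mean upper quartile; for
#' each sample, genes expressed in both libraries contribute a log-ratio
#' (M) and average log-abundance (A); the most extreme 30\% of M values and
#' 5\% of A values are trimmed on each side, and the factor is two to the
#' power of the precision-weighted mean of the surviving M values. Factors
#' are normalised so their geometric mean is 1.
#'
#' @param counts gene-by-sample count matrix with at least one non-zero
#'   entry per column.
#' @param ref optional reference column (index or name); by default chosen
#'   by the upper-quartile rule.
#' @param trimM,trimA two-sided trim fractions for log-ratios and
#'   log-abundances.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmmFactors <- function(counts, ref = NULL, trimM = 0.30, trimA = 0.05) {
  counts <- as.matrix(counts)
  N <- colSums(counts)
  if (any(N == 0)) stop("zero-count column(s): ",
                        paste(which(N == 0), collapse = ", "))
  if (is.null(ref)) {
    f75 <- apply(counts, 2L, function(x) quantile(x / sum(x), 0.75))
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) ref <- match(ref, colnames(counts))
  yr <- counts[, ref]
  Nr <- N[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]
    keep <- y > 0 & yr > 0
    if (!any(keep)) return(1)
    M <- log2((y[keep] / N[j]) / (yr[keep] / Nr))
    A <- 0.5 * log2((y[keep] / N[j]) * (yr[keep] / Nr))
    v <- (N[j] - y[keep]) / (N[j] * y[keep]) + (Nr - yr[keep]) / (Nr * yr[keep])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trimM) + 1L; hiM <- n + 1L - loM
    loA <- floor(n * trimA) + 1L; hiA <- n + 1L - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Normalised log2 expression values
#'
#' Counts per million on the effective library size (column total times its
#' TMM factor), with a pseudocount added before the log:
#' \eqn{\log_2((y + c) / (N \cdot f) \cdot 10^6)}. Monotone in counts
#' within a sample and finite everywhere for \eqn{c > 0}.
#'
#' @param counts gene-by-sample count matrix.
#' @param factors per-sample normalisation factors from [tmmFactors()];
#'   defaults to computing them.
#' @param pseudocount added to every count before the log (default 0.5).
#' @return log2-scale expression matrix with the factors attached as
#'   attribute \code{"normFactors"}.
#' @export
normalizedLog2 <- function(counts, factors = NULL, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- tmmFactors(counts)
  effLib <- colSums(counts) * factors
  out <- log2(sweep(counts + pseudocount, 2L, effLib, "/") * 1e6)
  attr(out, "normFactors") <- factors
  out
}

#' Dynamic range of a gene's expression
#'
#' Ratio between the 95th and 5th percentile of a gene's expression on the
#' linear scale, computed as \eqn{2^{q_{95} - q_5}} of the pooled log2
#' values across replicates, with linear-interpolation percentiles.
#'
#' @param values numeric vector of log2 expression values (all replicates
#'   pooled), length at least 2.
#' @return dynamic-range ratio, at least 1.
#' @export
dynamicRange <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  q <- quantile(values, c(0.05, 0.95), type = 7, names = FALSE)
  2^(q[2L] - q[1L])
}

#' Assemble a kymograph heat-map grid
#'
#' Arranges one value per sample into a (time bin, position index) tile
#' grid: each sample is one tile, later times may have more positions
#' (the grid is ragged), and tiles with no sample are flagged missing, not
#' zero-filled. Duplicate (time, position) pairs within a replicate are an
#' error.
#'
#' @param values numeric vector, one value per sample (in annotation
#'   order), or a named vector matched against \code{annotations$sample_id}.
#' @param annotations data.frame with columns \code{time} and
#'   \code{position} (and optionally \code{sample_id}, \code{replicate}).
#' @return data.frame with columns \code{sample_id}, \code{time},
#'   \code{position}, \code{time_bin}, \code{position_index}, \code{value};
#'   the full-grid missing tiles are attached as attribute
#'   \code{"missing"}.
#' @export
assembleKymograph <- function(values, annotations) {
  ann <- as.data.frame(annotations)
  stopifnot(all(c("time", "position") %in% names(ann)))
  if (is.null(ann$sample_id)) ann$sample_id <- seq_len(nrow(ann))
  if (!is.null(names(values)))
    values <- values[as.character(ann$sample_id)]
  if (length(values) != nrow(ann))
    stop("one value per annotation row is required")
  key <- paste(ann$time, ann$position, sep = "@")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (time, position) tiles: ", paste(dup, collapse = "; "))
  }
  tlev <- sort(unique(ann$time))
  plev <- sort(unique(ann$position))
  out <- data.frame(
    sample_id = ann$sample_id,
    time = ann$time,
    position = ann$position,
    time_bin = match(ann$time, tlev),
    position_index = match(ann$position, plev),
    value = as.numeric(values)
  )
  full <- expand.grid(time_bin = seq_along(tlev),
                      position_index = seq_along(plev))
  present <- paste(out$time_bin, out$position_index)
  attr(out, "missing") <-
    full[!(paste(full$time_bin, full$position_index) %in% present), ,
         drop = FALSE]
  out
}

#' Read / write count matrices
#'
#' \code{readCountMatrix} reads either a TSV (genes in rows, first column
#' gene ids, remaining columns samples) or a MatrixMarket \code{.mtx} file
#' with sidecar row/column name files (\code{<stem>.genes.txt},
#' \code{<stem>.samples.txt}).
#'
#' @param path file path (\code{.tsv} or \code{.mtx}).
#' @return integer gene-by-sample matrix with dimnames.
#' @export
readCountMatrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".genes.txt"))
    colnames(m) <- readLines(paste0(stem, ".samples.txt"))
    m
  } else {
    d <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d[[1L]]
    m
  }
}

#' @rdname readCountMatrix
#' @param counts matrix to write.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @export
writeCountMatrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts), paste0(stem, ".genes.txt"))
    writeLines(colnames(counts), paste0(stem, ".samples.txt"))
  } else {
    d <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
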