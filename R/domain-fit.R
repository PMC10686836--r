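#' Fit a shared exponential boundary across replicates
#'
#' Jointly fits \eqn{b(t) = b_0^{(k)} e^{t/\tau}} to the boundary-radius
#' observations of all replicates by minimising the summed squared loss
#' \deqn{L(\tau, b_0^{(1)}, \dots) = \sum_k \sum_l
#'   \left(b_l^{(k)} - b_0^{(k)} e^{t_l^{(k)}/\tau}\right)^2}
#' with one shared growth timescale \eqn{\tau} and one intercept per
#' replicate. For fixed \eqn{\tau} the optimal intercepts are linear
#' least-squares solutions, so the fit profiles them out analytically and
#' minimises the residual over \eqn{\tau} alone (deterministic, no random
#' initialisation). Time shifts mapping all replicates onto a common
#' non-dimensional domain are then computed: the reference replicate
#' \eqn{r} is the one with the largest \eqn{b_0} (ties broken by lowest
#' replicate order), its shift is its first sampling time
#' \eqn{t_s^{(r)} = t_0^{(r)}}, the common scale is
#' \eqn{b_0 = b_0^{(r)} e^{t_s^{(r)}/\tau}}, and the other shifts are
#' \eqn{t_s^{(k)} = \tau[\log b_0^{(r)} - \log b_0^{(k)}] + t_s^{(r)}}.
#'
#' @param observations data.frame with columns \code{replicate},
#'   \code{time} (h) and \code{radius} (mm); at least two observations per
#'   replicate, radii positive, times strictly increasing within replicate.
#' @param Tmax optional override for the common non-dimensional extent
#'   \eqn{T}; by default the maximum non-dimensional time present in all
#'   replicates' observations.
#'
#' @return a [SwarmDomain].
#' @examples
#' tt <- seq(0, 6, by = 0.5)
#' obs <- data.frame(replicate = "r1", time = tt,
#'                   radius = 0.5 * exp(tt / 1.5))
#' fitBoundary(obs)
#' @export
fitBoundary <- function(observations, Tmax = NULL) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("replicate", "time", "radius") %in% names(obs)))
  if (any(obs$radius <= 0))
    stop("boundary radii must be positive")
  reps <- unique(as.character(obs$replicate))
  byrep <- split(obs, factor(obs$replicate, levels = reps))
  if (any(vapply(byrep, nrow, 0L) < 2L))
    stop("need at least 2 boundary observations per replicate")
  for (d in byrep)
    if (any(diff(d$time) <= 0))
      stop("times must be strictly increasing within each replicate")

  # profile the intercepts: for fixed tau, b0 = sum(b*E) / sum(E^2),
  # E = exp(t / tau); residual sum of squares is then a 1-D function of tau
  rssProfile <- function(tau) {
    rss <- 0
    for (d in byrep) {
      E <- exp(d$time / tau)
      b0 <- sum(d$radius * E) / sum(E^2)
      rss <- rss + sum((d$radius - b0 * E)^2)
    }
    rss
  }
  # crude bracket from per-replicate log-linear slopes
  slopes <- vapply(byrep, function(d) {
    stats::coef(stats::lm(log(d$radius) ~ d$time))[2L]
  }, 0)
  tau0 <- if (any(slopes > 0)) 1 / max(mean(slopes[slopes > 0]), 1e-6) else
    diff(range(obs$time)) + 1
  grid <- tau0 * exp(seq(log(0.05), log(20), length.out = 60L))
  vals <- vapply(grid, rssProfile, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(rssProfile, interval = c(lo, hi),
                         tol = .Machine$double.eps^0.5)
  tau <- opt$minimum
  b0 <- vapply(byrep, function(d) {
    E <- exp(d$time / tau)
    sum(d$radius * E) / sum(E^2)
  }, 0)
  names(b0) <- reps

  r <- reps[which.max(b0)]   # ties: which.max takes the first (lowest order)
  ts_r <- min(byrep[[r]]$time)
  shifts <- tau * (log(b0[[r]]) - log(b0)) + ts_r
  names(shifts) <- reps
  b0Common <- b0[[r]] * exp(ts_r / tau)

  if (is.null(Tmax)) {
    Tmax <- min(vapply(reps, function(k) {
      max((byrep[[k]]$time - shifts[[k]]) / tau)
    }, 0))
    if (Tmax <= 0)
      stop("replicates share no common non-dimensional time range")
  }
  new("SwarmDomain", tau = tau, b0 = b0, timeShifts = shifts,
      b0Common = b0Common, Tmax = Tmax, reference = r)
}

#' Map sample annotations onto the common non-dimensional domain
#'
#' Applies \eqn{\tilde t = (t - t_s^{(k)})/\tau} and
#' \eqn{\tilde p = p / b_0} to every annotation and evaluates domain
#' membership \eqn{0 \le \tilde t \le T,\; 0 \le \tilde p \le e^{\tilde t}}
#' (boundary inclusive on all four constraints, with a small relative
#' tolerance guarding floating-point round-off). Points outside the common
#' domain are flagged, not dropped; downstream spectral fitting uses only
#' in-domain points.
#'
#' @param annotations data.frame with columns \code{replicate}, \code{time}
#'   (h) and \code{position} (mm); extra columns are carried through.
#' @param domain a [SwarmDomain].
#' @param tol relative tolerance for boundary-inclusive comparisons.
#'
#' @return the input data.frame with added columns \code{t_tilde},
#'   \code{p_tilde}, \code{in_domain}.
#' @export
nondimensionalize <- function(annotations, domain, tol = 1e-9) {
  ann <- as.data.frame(annotations)
  stopifnot(all(c("replicate", "time", "position") %in% names(ann)))
  reps <- as.character(ann$replicate)
  missing <- setdiff(unique(reps), names(domain@timeShifts))
  if (length(missing))
    stop("no time shift for replicate(s): ", paste(missing, collapse = ", "))
  shifts <- domain@timeShifts[reps]
  ann$t_tilde <- (ann$time - shifts) / domain@tau
  ann$p_tilde <- ann$position / domain@b0Common
  Tm <- domain@Tmax
  eps <- tol * max(1, Tm)
  ann$in_domain <- ann$t_tilde >= -eps & ann$t_tilde <= Tm + eps &
    ann$p_tilde >= -eps &
    ann$p_tilde <= exp(ann$t_tilde) * (1 + tol) + eps
  ann
}

#' Serialise / restore a domain fit
#'
#' @param domain a [SwarmDomain].
#' @param path file to write (JSON).
#' @return \code{writeSwarmDomain} returns \code{path} invisibly;
#'   \code{readSwarmDomain} returns a [SwarmDomain].
#' @export
writeSwarmDomain <- function(domain, path) {
  x <- list(tau = domain@tau, b0 = as.list(domain@b0),
            timeShifts = as.list(domain@timeShifts),
            b0Common = domain@b0Common, Tmax = domain@Tmax,
            reference = domain@reference)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSwarmDomain
#' @export
readSwarmDomain <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SwarmDomain", tau = x$tau, b0 = unlist(x$b0),
      timeShifts = unlist(x$timeShifts), b0Common = x$b0Common,
      Tmax = x$Tmax, reference = x$reference)
}
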