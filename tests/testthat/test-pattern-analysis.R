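setupFit <- function() {
  b <- swarmBasis(2, M = 5L, nNodes = c(32L, 32L))
  grid <- domainGrid(b, nt = 10L, np = 6L)
  X <- evaluateDesign(b, grid)
  list(basis = b, grid = grid, X = X)
}

test_that("rescaling standardises level and scale as defined", {
  s <- setupFit()
  p0 <- constantValue(s$basis)
  # constant gene: k0 = 0 after rescale (c0 = mu / p0), flagged constant
  gConst <- rep(2.5, nrow(s$X))
  gVar <- drop(s$X %*% c(1, 0.5, 0, -0.3, 0, 0))
  expr <- rbind(gConst, gVar)
  cf <- fitSpectral(expr, s$X)
  rs <- rescaleCoefficients(cf, expr, p0)
  expect_true(rs$constant[1])
  expect_false(rs$constant[2])
  expect_equal(cf[1, 1] * p0, 2.5, tolerance = 1e-9)
  # scaling expression by a > 0 leaves k unchanged; shifting leaves
  # k_{m>0} unchanged
  a <- 3.7; shift <- 1.9
  exprS <- rbind(gVar * a, gVar + shift)
  cfS <- fitSpectral(exprS, s$X)
  rsS <- rescaleCoefficients(cfS, exprS, p0)
  expect_lt(max(abs(rsS$k[1, ] - rs$k[2, ])), 1e-9)
  expect_lt(max(abs(rsS$k[2, ] - rs$k[2, ])), 1e-9)
})

test_that("pattern scores behave at the noise-free extremes", {
  s <- setupFit()
  set.seed(8)
  gNoise <- rnorm(nrow(s$X), mean = 5, sd = 0.1)
  gExact <- 5 + 2 * s$X[, 2L]            # mu + sigma-scaled P1: exact fit
  expr <- rbind(gNoise, gExact)
  cf <- fitSpectral(expr, s$X)
  sc <- scorePatterns(expr, cf, s$X, p0 = constantValue(s$basis))
  # pure-noise gene: negligible pattern, tiny ranking
  expect_lt(sc$P[1], 0.5)
  expect_lt(sc$R[1], 0.01)
  # exactly representable gene: E at round-off, R = Inf sentinel
  expect_lt(sc$E[2], 1e-15)
  expect_true(is.infinite(sc$R[2]))
})

test_that("ranking is invariant under per-gene affine transforms", {
  s <- setupFit()
  set.seed(9)
  expr <- rbind(
    drop(s$X %*% c(4, 1, 0, 0.5, 0, 0)) + rnorm(nrow(s$X), 0, 0.3),
    drop(s$X %*% c(2, 0, -1, 0, 0.2, 0)) + rnorm(nrow(s$X), 0, 0.5))
  score0 <- function(e) {
    cf <- fitSpectral(e, s$X)
    scorePatterns(e, cf, s$X, p0 = constantValue(s$basis))$R
  }
  R0 <- score0(expr)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); c0 <- runif(1, -20, 20)
    expect_equal(score0(a * expr + c0), R0, tolerance = 1e-8)
  }
})

test_that("weighted-median selection matches brute-force enumeration", {
  expect_equal(sum(selectPatterned(c(1, 1, 1, 1))), 2L)
  expect_equal(unname(selectPatterned(c(0, 0, 0, 10))),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_true(selectPatterned(5))          # single gene is selected
  expect_equal(sum(selectPatterned(c(0, 0))), 0L)
  set.seed(12)
  for (i in 1:20) {
    R <- rexp(sample(3:40, 1))
    if (i %% 4 == 0) R[sample(length(R), 2)] <- 0
    if (i %% 5 == 0) R[1] <- Inf
    expect_identical(unname(selectPatterned(R)), bruteSelect(R))
  }
  # selected genes always carry at least half the (finite) total
  for (i in 1:10) {
    R <- rexp(30)
    sel <- selectPatterned(R)
    expect_gte(sum(R[sel]) / sum(R), 0.5)
  }
})

test_that("noise-free cohort ranking separates patterned genes perfectly", {
  st <- simSwarmStudy(nFlat = 60L, nPatterned = 25L, noiseSd = 0,
                      nNodes = c(32L, 32L), seed = 21L)
  ann <- st$annotations
  reps <- unique(ann$replicate)
  design <- do.call(rbind, lapply(reps, function(r)
    evaluateDesign(st$basis, ann[ann$replicate == r,
                                 c("t_tilde", "p_tilde")])))
  expr <- do.call(cbind, lapply(reps, function(r)
    st$expression[, ann$replicate == r, drop = FALSE]))
  fit <- spectralFit(expr, design, st$basis)
  sc <- patternScores(fit)
  # flat genes are exactly constant at noise 0: flagged, never selected
  expect_true(all(sc$constant[!st$patterned]))
  # patterned genes are exactly representable: R = Inf, all selected
  expect_true(all(is.infinite(sc$R[st$patterned])))
  recall <- sum(sc$selected & st$patterned) / sum(st$patterned)
  expect_gte(recall, 0.95)
  # AUROC of R against the planted labels (constant genes rank lowest)
  Rvals <- sc$R
  Rvals[sc$constant] <- 0
  expect_equal(aurocOf(Rvals, st$patterned), 1.0)
})

test_that("cosine similarity has the defining geometry", {
  k <- rbind(a = c(9, 1, 2, 3, 0, 0),
             b = c(-4, 1, 2, 3, 0, 0),       # same pattern, other level
             c = c(0, -1, -2, -3, 0, 0),     # negated pattern
             d = c(5, 3, 0, -1, 0, 0))       # pattern orthogonal to a
  S <- cosineSimilarity(k)
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_equal(S, t(S))
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], -1)
  expect_equal(S["a", "d"], 0, tolerance = 1e-12)
  expect_true(all(S >= -1 & S <= 1))
  # zero pattern vectors are dropped with a warning
  k2 <- rbind(k, e = c(7, 0, 0, 0, 0, 0))
  expect_warning(S2 <- cosineSimilarity(k2), "zero pattern")
  expect_equal(nrow(S2), 4L)
})

test_that("k-medoids recovers planted families and duplicates co-cluster", {
  st <- simSwarmStudy(nFlat = 0L, nPatterned = 60L, nFamilies = 2L,
                      noiseSd = 0, nNodes = c(32L, 32L), seed = 31L)
  k <- st$coefficients
  k[, 1] <- 0
  S <- cosineSimilarity(k)
  cl <- clusterPatterns(S, 2)
  expect_equal(adjustedRand(cl$labels, st$family), 1)
  # duplicated gene always joins its twin's cluster
  k2 <- rbind(k, dup = k[1, ])
  S2 <- cosineSimilarity(k2)
  cl2 <- clusterPatterns(S2, 2)
  expect_equal(unname(cl2$labels["dup"]), unname(cl2$labels[1]))
  # permutation of the input order gives the identical partition
  set.seed(1)
  perm <- sample(nrow(S))
  clp <- clusterPatterns(S[perm, perm], 2)
  expect_equal(adjustedRand(clp$labels[rownames(S)], cl$labels), 1)
  expect_error(clusterPatterns(S, nrow(S) + 1L), "more clusters")
})

test_that("elbow curve is non-increasing with zero cost at k = n", {
  st <- simSwarmStudy(nFlat = 0L, nPatterned = 36L, nFamilies = 6L,
                      noiseSd = 0, nNodes = c(32L, 32L), seed = 32L)
  k <- st$coefficients; k[, 1] <- 0
  S <- cosineSimilarity(k)
  ec <- elbowCurve(S, 2:10)
  expect_true(all(diff(ec$cost) <= 1e-8))
  expect_equal(attr(ec, "elbow"), 6L)
  expect_equal(clusterPatterns(S, nrow(S))$cost, 0)
})

test_that("mean cluster patterns recover family templates", {
  st <- simSwarmStudy(nFlat = 0L, nPatterned = 30L, nFamilies = 6L,
                      noiseSd = 0, nNodes = c(32L, 32L), seed = 33L)
  grid <- domainGrid(st$basis, nt = 15L, np = 10L)
  fam1 <- which(st$family == 1L)
  mp <- meanPattern(st$coefficients[fam1, ], st$basis, grid)
  expect_true(all(is.finite(mp$value)))
  # cosine similarity between the mean member pattern and one member
  mean1 <- colMeans(st$coefficients[fam1, -1])
  one1 <- st$coefficients[fam1[1], -1]
  cosim <- sum(mean1 * one1) / sqrt(sum(mean1^2) * sum(one1^2))
  expect_gt(cosim, 0.99)
  # singleton cluster reproduces that gene's reconstruction
  mp1 <- meanPattern(st$coefficients[fam1[1], , drop = FALSE], st$basis,
                     grid)
  expect_equal(mp1$value,
               reconstructField(st$coefficients[fam1[1], ], st$basis,
                                grid))
  # mean of k and -k is the zero field
  kk <- rbind(st$coefficients[fam1[1], ], -st$coefficients[fam1[1], ])
  expect_equal(meanPattern(kk, st$basis, grid)$value, rep(0, nrow(grid)))
})

test_that("metric MDS embeds known geometries faithfully", {
  # three equidistant items form an equilateral triangle
  S <- matrix(0.4, 3, 3); diag(S) <- 1
  em <- mdsEmbed(S)
  d <- dist(em$coords)
  expect_equal(max(d) / min(d), 1, tolerance = 1e-6)
  expect_equal(as.numeric(d), rep(0.6, 3), tolerance = 1e-4)
  # identical items land on (near-)identical coordinates
  S2 <- rbind(c(1, 1, 0.2), c(1, 1, 0.2), c(0.2, 0.2, 1))
  em2 <- mdsEmbed(S2)
  expect_lt(sqrt(sum((em2$coords[1, ] - em2$coords[2, ])^2)), 1e-6)
  # rank correlation between input and embedded distances on families
  st <- simSwarmStudy(nFlat = 0L, nPatterned = 30L, nFamilies = 6L,
                      noiseSd = 0.2, nNodes = c(32L, 32L), seed = 34L)
  k <- st$coefficients; k[, 1] <- 0
  S3 <- cosineSimilarity(k)
  em3 <- mdsEmbed(S3)
  dd <- as.numeric(dist(em3$coords))
  d0 <- as.numeric(as.dist(1 - S3))
  expect_gt(cor(dd, d0, method = "spearman"), 0.8)
  # deterministic
  em3b <- mdsEmbed(S3)
  expect_identical(em3$coords, em3b$coords)
})

test_that("neighbour-function counts follow the stated rules", {
  coords <- rbind(diag(0.1 * 1:10) %*% matrix(1, 10, 2))
  rownames(coords) <- sprintf("g%02d", 1:10)
  ft <- data.frame(gene = rownames(coords),
                   category = rep(c("metabolism", "motility"), each = 5))
  # n = 1: the single nearest gene's category
  n1 <- neighborFunctions(coords, c(0, 0), ft, n = 1L, minCategory = 1L)
  expect_identical(names(n1), "metabolism")
  expect_equal(unname(n1), 1L)
  # all genes one category
  ft1 <- data.frame(gene = rownames(coords), category = "metabolism")
  nAll <- neighborFunctions(coords, c(0, 0), ft1, n = 10L,
                            minCategory = 1L)
  expect_equal(unname(nAll), 10L)
  # small categories merge into "other"; counts sum to n
  ft2 <- data.frame(gene = rownames(coords),
                    category = c(rep("metabolism", 8), "rare1", "rare2"))
  n2 <- neighborFunctions(coords, c(0, 0), ft2, n = 10L, minCategory = 2L)
  expect_equal(sum(n2), 10L)
  expect_true("other" %in% names(n2))
  expect_equal(unname(n2["other"]), 2L)
  # a metabolic cluster adjacent to the point dominates the counts
  n3 <- neighborFunctions(coords, c(0, 0), ft, n = 5L, minCategory = 1L)
  expect_equal(unname(n3["metabolism"]), 5L)
  # ties at the n-th distance break by gene id order
  tied <- rbind(a = c(1, 0), b = c(0, 1), c = c(-1, 0))
  ftT <- data.frame(gene = c("a", "b", "c"),
                    category = c("ca", "cb", "cc"))
  nT <- neighborFunctions(tied, c(0, 0), ftT, n = 2L, minCategory = 1L)
  expect_identical(sort(names(nT)), c("ca", "cb"))
  expect_error(neighborFunctions(tied, c(0, 0), ftT, n = 5L), "exceeds")
})
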