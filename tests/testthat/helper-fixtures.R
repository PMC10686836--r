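# Shared fixtures: small, deterministic, built in code.

# brute-force inner product on a fine midpoint grid (independent oracle
# for the Gauss-Legendre quadrature)
bruteInnerProduct <- function(f, g, Tmax, nt = 2000L, np = 400L) {
  dt <- Tmax / nt
  tt <- (seq_len(nt) - 0.5) * dt
  total <- 0
  for (t1 in tt) {
    up <- exp(t1)
    dp <- up / np
    pp <- (seq_len(np) - 0.5) * dp
    total <- total + sum(exp(-t1) * f(t1, pp) * g(t1, pp)) * dp * dt
  }
  total
}

# closed-form monomial inner product on the swarm domain:
# <t^a p^b, t^c p^d> = 1/(b+d+1) * integral_0^T t^(a+c) e^((b+d) t) dt,
# with the t-integral by the exact recursion
# I(A, B) = (T^A e^(BT) - A I(A-1, B)) / B,  I(A, 0) = T^(A+1)/(A+1)
exactMonomialIP <- function(a, b, c, d, Tmax) {
  A <- a + c
  B <- b + d
  texp <- function(A, B) {
    if (B == 0) return(Tmax^(A + 1) / (A + 1))
    if (A == 0) return((exp(B * Tmax) - 1) / B)
    (Tmax^A * exp(B * Tmax) - A * texp(A - 1, B)) / B
  }
  texp(A, B) / (B + 1)
}

# exact Gram matrix of a polynomial basis from the closed forms
exactGram <- function(basis) {
  ex <- basis@exponents
  C <- basis@coefficients
  n <- nrow(ex)
  Gm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    Gm[i, j] <- exactMonomialIP(ex[i, 1], ex[i, 2], ex[j, 1], ex[j, 2],
                                basis@Tmax)
  C %*% Gm %*% t(C)
}

# brute-force application of the weighted-median selection rule
bruteSelect <- function(R) {
  n <- length(R)
  inf <- is.infinite(R)
  fin <- is.finite(R)
  sel <- inf
  total <- sum(R[fin])
  if (total > 0) {
    ord <- order(R[fin])
    Nc <- 0L
    for (i in seq_len(sum(fin))) {
      if (sum(R[fin][ord][seq_len(i)]) / total <= 0.5) Nc <- i
    }
    if (Nc < sum(fin))
      sel[which(fin)[ord][(Nc + 1L):sum(fin)]] <- TRUE
  }
  sel
}

# adjusted Rand index between two label vectors (closed form from the
# pair-counting contingency table)
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

# area under the ROC curve via the rank-sum identity
aurocOf <- function(score, truth) {
  r <- rank(score)
  npos <- sum(truth)
  nneg <- sum(!truth)
  (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# small shared synthetic study (cached per test run)
tinyStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simSwarmStudy(nFlat = 40L, nPatterned = 20L,
                              nNodes = c(32L, 32L), seed = 11L)
    cache
  }
})
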