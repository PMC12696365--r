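# Shared fixtures and independent oracles, all built in code.

straightChain <- function(n, spacing = 0.38) {
  BeadChain(cbind(seq_len(n) * spacing, 0, 0))
}

# proper rotation matrix from a seeded QR decomposition
randomRotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force O(n^2) double loop; oracle for maxEuclidean
bruteMaxDist <- function(x) {
  best <- 0
  for (i in seq_len(nrow(x) - 1))
    for (j in (i + 1):nrow(x))
      best <- max(best, sqrt(sum((x[i, ] - x[j, ])^2)))
  best
}

# reduced chi2 with optimal scale, written independently of the package
oracleChi2 <- function(Ie, Im, sig) {
  w <- 1 / sig^2
  cc <- sum(Ie * Im * w) / sum(Im^2 * w)
  sum(((Ie - cc * Im) / sig)^2) / (length(Ie) - 1)
}

# exhaustive enumeration of every multiset of pool columns up to maxSize;
# oracle for the genetic algorithm on tiny pools
enumerateBestChi2 <- function(M, Ie, sig, maxSize) {
  P <- ncol(M)
  best <- Inf
  bestW <- NULL
  counts <- function(p, left, acc) {
    if (p == P) {
      k <- c(acc, left)
      if (sum(k) == 0) return(invisible(NULL))
      Im <- as.vector(M %*% k) / sum(k)
      c2 <- oracleChi2(Ie, Im, sig)
      if (c2 < best) {
        best <<- c2
        bestW <<- k / sum(k)
      }
      return(invisible(NULL))
    }
    for (ki in 0:left) counts(p + 1, left - ki, c(acc, ki))
  }
  for (m in 1:maxSize) counts(1, m, integer(0))
  list(chi2 = best, weights = bestW)
}

# tight shell of beads enclosing the origin (for burial tests)
enclosingShell <- function(radius = 0.5, n = 80) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(r * cos(phi), r * sin(phi), z)
}
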