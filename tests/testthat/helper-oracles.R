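# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorised code paths: scalar loops and closed forms only.

# Scalar pairwise GIP kernel: loop over pairs, exp(-gamma * squared distance).
gipOracle <- function(profiles, gammaPrime = 1) {
  n <- nrow(profiles)
  gamma <- gammaPrime / mean(rowSums(profiles^2))
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d2 <- sum((profiles[i, ] - profiles[j, ])^2)
    S[i, j] <- exp(-gamma * d2)
  }
  S
}

# Closed form of the constant-source label recursion:
#   L^k = (1 - (1-a)^k) S L0 + (1-a)^k L0
closedFormIterate <- function(S, L0, alpha, k) {
  SL0 <- S %*% L0
  (1 - (1 - alpha)^k) * SL0 + (1 - alpha)^k * L0
}

# Geometric partial sum of the iterates, L^0 + ... + L^n:
#   (n+1) S L0 + (L0 - S L0) * (1 - (1-a)^{n+1}) / a
closedFormScoreSum <- function(S, L0, alpha, n) {
  SL0 <- S %*% L0
  (n + 1) * SL0 + (L0 - SL0) * (1 - (1 - alpha)^(n + 1)) / alpha
}

# Predicted iteration count from the exact geometric decay of the L1 change:
# change_k = (1-a)^{k-1} * change_1; stop at the first k with change_k < P.
predictedIterations <- function(S, L0, alpha, thresholdP, maxIter = 1000) {
  change1 <- sum(abs(alpha * (S %*% L0 - L0)))
  k <- 1
  while (change1 * (1 - alpha)^(k - 1) >= thresholdP && k < maxIter) k <- k + 1
  k
}

# Brute-force pairwise AUC: enumerate (positive, negative) pairs.
aucOracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Random sparse binary matrix with no all-zero guarantee issues avoided by
# rejection (keeps at least one 1).
randomBinaryMatrix <- function(nr, nc, p = 0.3) {
  repeat {
    a <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (sum(a) >= 2) return(a)
  }
}

# Row-stochastic-over-Q matrix from a random kernel, for propagation tests.
randomSstar <- function(n, k = 0, mode = "literal") {
  a <- randomBinaryMatrix(n, n + 3, 0.4)
  as.matrix(neighborNormalize(gipKernel(a), k = k, mode = mode))
}

writeToyFile <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
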