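test_that("rank AUC matches hand-enumerated examples", {
  expect_equal(aucRank(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(aucRank(0.5, 0.5), 0.5)
  expect_equal(aucRank(c(0.7, 0.3), c(0.5, 0.1)), 0.75)
  expect_error(aucRank(numeric(0), 1), "non-empty")
  expect_error(aucRank(1, numeric(0)), "non-empty")
})

test_that("rank AUC agrees with the brute-force pair-counting oracle", {
  set.seed(51)
  for (i in 1:20) {
    pos <- round(runif(sample(1:10, 1)), 2)  # rounding forces ties
    neg <- round(runif(sample(1:10, 1)), 2)
    expect_equal(aucRank(pos, neg), aucOracle(pos, neg), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  for (i in 1:5) {
    pos <- runif(20); neg <- runif(30)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = c(rep(1, 20), rep(0, 30)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE)))
    expect_equal(aucRank(pos, neg), ref, tolerance = 1e-12)
  }
})

test_that("rank AUC is invariant under strictly monotone score transforms", {
  set.seed(53)
  pos <- runif(15); neg <- runif(25)
  base <- aucRank(pos, neg)
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3,
                 function(x) rank(x, ties.method = "average"))) {
    all <- f(c(pos, neg))
    expect_equal(aucRank(all[1:15], all[-(1:15)]), base, tolerance = 1e-12)
  }
})

test_that("ROC curve has the documented shape and trapezoidal area", {
  # perfect separation passes through (0, 1)
  roc <- rocPoints(c(0.9, 0.8), c(0.1, 0.2))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(rocAuc(roc), 1)
  # all-identical scores: diagonal, area one half
  rocFlat <- rocPoints(rep(0.4, 3), rep(0.4, 5))
  expect_equal(rocAuc(rocFlat), 0.5)
  # endpoints
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  # the 2+2 example
  expect_equal(rocAuc(rocPoints(c(0.7, 0.3), c(0.5, 0.1))), 0.75)
})

test_that("trapezoidal ROC area equals rank AUC on random score sets", {
  set.seed(54)
  for (i in 1:50) {
    pos <- round(runif(sample(2:12, 1)), 1)
    neg <- round(runif(sample(2:12, 1)), 1)
    expect_equal(rocAuc(rocPoints(pos, neg)), aucRank(pos, neg),
                 tolerance = 1e-12)
    expect_true(all(diff(rocPoints(pos, neg)$tpr) >= 0))
    expect_true(all(diff(rocPoints(pos, neg)$fpr) >= 0))
  }
})

# Independent miniature pipeline used as the LOOCV oracle: scalar kernel,
# plain normalisation (K = 0), direct iteration, fusion, win fractions.
loocvOracle <- function(a, alpha = 0.2, beta = 0.75, P = 1e-12) {
  known <- which(a == 1, arr.ind = TRUE)
  negPool <- which(a == 0, arr.ind = TRUE)
  iterate <- function(S, L0) {
    src <- alpha * (S %*% L0); Lp <- L0; tot <- L0
    repeat {
      Ln <- src + (1 - alpha) * Lp
      ch <- sum(abs(Ln - Lp)); tot <- tot + Ln; Lp <- Ln
      if (ch < P) break
    }
    tot
  }
  norm0 <- function(S) { diag(S) <- 0; S / rowSums(S) }
  gipF <- function(p) {  # scalar kernel with the gamma fallback
    m <- mean(rowSums(p^2)); g <- if (m == 0) 1 else 1 / m
    n <- nrow(p); S <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) S[i, j] <- exp(-g * sum((p[i, ] - p[j, ])^2))
    S
  }
  wins <- apply(known, 1, function(e) {
    at <- a; at[e[1], e[2]] <- 0
    w <- beta * t(iterate(norm0(gipF(t(at))), t(at))) +
      (1 - beta) * iterate(norm0(gipF(at)), at)
    s <- w[e[1], e[2]]; ns <- w[negPool]
    mean(s > ns) + 0.5 * mean(s == ns)
  })
  mean(wins)
}

test_that("LOOCV on the hand-checkable 2x2 toy matches the independent oracle", {
  a <- rbind(c(1L, 1L), c(1L, 0L))
  dimnames(a) <- list(c("d1", "d2"), c("m1", "m2"))
  A <- associationMatrix(a)
  r <- loocv(A, lpConfig(kNeighbors = 0L))
  expect_equal(r@folds, 3L)
  expect_equal(nrow(r@details), 3L)
  expect_equal(auc(r), loocvOracle(a), tolerance = 1e-10)
  expect_true(all(r@details$winFraction %in% c(0, 0.5, 1) |
                    (r@details$winFraction >= 0 & r@details$winFraction <= 1)))
})

test_that("LOOCV matches the independent oracle on a random instance", {
  set.seed(55)
  a <- randomBinaryMatrix(5, 7, 0.35)
  A <- associationMatrix(a)
  r <- loocv(A, lpConfig(kNeighbors = 0L))
  expect_equal(auc(r), loocvOracle(a), tolerance = 1e-10)
})

test_that("degenerate cross-validation inputs are rejected", {
  allOnes <- associationMatrix(matrix(1L, 3, 3))
  expect_error(loocv(allOnes), "unknown pairs")
  single <- associationMatrix(rbind(c(1L, 0L), c(0L, 0L)))
  expect_error(loocv(single), "at least 2")
  a <- associationMatrix(rbind(c(1L, 1L), c(1L, 0L)))
  expect_error(kfoldCV(a, folds = 5, repeats = 1, config = lpConfig(kNeighbors = 0L)),
               "exceeds")
  expect_error(kfoldCV(a, folds = 1), "folds")
})

test_that("cross-validation is exactly reproducible for a fixed seed", {
  sim <- simulateAssociations(10, 14, 2, 0.5, 0.02, seed = 2)
  cfg <- lpConfig(kNeighbors = 3L)
  r1 <- kfoldCV(sim$matrix, folds = 4, repeats = 2, seed = 77, config = cfg)
  r2 <- kfoldCV(sim$matrix, folds = 4, repeats = 2, seed = 77, config = cfg)
  expect_identical(r1@repeats, r2@repeats)
  expect_identical(r1@details, r2@details)
  expect_equal(r1@aucSd, sd(r1@repeats))
  l1 <- loocv(sim$matrix, cfg)
  l2 <- loocv(sim$matrix, cfg)
  expect_identical(l1@perFold, l2@perFold)
})

test_that("k-fold with one pair per fold reproduces LOOCV", {
  set.seed(56)
  a <- randomBinaryMatrix(4, 5, 0.25)
  while (sum(a) < 4 || sum(a) > 6) a <- randomBinaryMatrix(4, 5, 0.25)
  A <- associationMatrix(a)
  cfg <- lpConfig(kNeighbors = 0L)
  lr <- loocv(A, cfg)
  kr <- kfoldCV(A, folds = nAssociations(A), repeats = 1, seed = 5,
                config = cfg)
  expect_equal(kr@auc, lr@auc, tolerance = 1e-12)
})

test_that("pooled LOOCV ranking also lies in [0, 1] and tracks per-fold AUC", {
  sim <- simulateAssociations(8, 10, 2, 0.5, 0.05, seed = 6)
  cfg <- lpConfig(kNeighbors = 2L)
  perfold <- loocv(sim$matrix, cfg, pooling = "perfold")
  pooled <- loocv(sim$matrix, cfg, pooling = "pooled")
  expect_true(pooled@auc >= 0 && pooled@auc <= 1)
  expect_equal(pooled@auc, perfold@auc, tolerance = 0.1)
})

test_that("a length-1 sweep grid returns its only value as the argmax", {
  sim <- simulateAssociations(8, 10, 2, 0.5, 0.05, seed = 9)
  tab <- parameterSweep(sim$matrix, "alpha", 0.3, protocol = "kfold",
                        config = lpConfig(kNeighbors = 2L),
                        folds = 3, repeats = 1, seed = 4)
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "best"), 0.3)
})

test_that("beta sweeps are flat when every fold is perfectly symmetric", {
  # identity adjacency: removing any diagonal edge keeps A symmetric and the
  # two networks identical, so WLPD = WLPM in every fold and beta cancels
  A <- associationMatrix(diag(1L, 4))
  tab <- parameterSweep(A, "beta", c(0.1, 0.5, 0.9), protocol = "loocv",
                        config = lpConfig(kNeighbors = 0L))
  expect_equal(max(tab$auc) - min(tab$auc), 0, tolerance = 1e-12)
})
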