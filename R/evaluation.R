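#' @include AllClasses.R propagation.R
NULL

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive score exceeds a randomly
#' chosen negative score, with ties counting one half (midrank convention).
#' Equals the trapezoidal area under the empirical ROC curve of
#' [rocPoints()].
#'
#' @param positiveScores,negativeScores non-empty numeric vectors.
#' @return AUC in [0, 1].
#' @examples
#' aucRank(c(0.7, 0.3), c(0.5, 0.1))  # 0.75
#' @export
aucRank <- function(positiveScores, negativeScores) {
  np <- length(positiveScores); nn <- length(negativeScores)
  if (np == 0L || nn == 0L)
    stop("both score vectors must be non-empty")
  r <- rank(c(positiveScores, negativeScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Empirical ROC curve
#'
#' True/false positive rates at every distinct score threshold (predicted
#' positive means score >= threshold), with the (0,0) and (1,1) endpoints.
#' The trapezoidal area under this curve equals [aucRank()] exactly.
#'
#' @inheritParams aucRank
#' @return data.frame with columns `threshold` (descending), `fpr`, `tpr`.
#' @export
rocPoints <- function(positiveScores, negativeScores) {
  if (length(positiveScores) == 0L || length(negativeScores) == 0L)
    stop("both score vectors must be non-empty")
  thr <- sort(unique(c(positiveScores, negativeScores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positiveScores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(negativeScores >= t), numeric(1))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fpr),
             tpr = c(0, tpr))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc a data.frame as returned by [rocPoints()].
#' @return area in [0, 1].
#' @export
rocAuc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

# Force the gamma fallback on inside CV: deleting test edges can zero out
# an entire profile set on tiny matrices, and a CV fold must not abort.
.cvConfig <- function(config) {
  config@gammaFallback <- TRUE
  config
}

# Score matrix for one CV fold: zero the test edges, optionally refit the
# similarity matrices on the reduced matrix, propagate, fuse.
.foldScores <- function(a, testIdx, config, refitSimilarity,
                        SDstarFull = NULL, SMstarFull = NULL) {
  aTrain <- a
  aTrain[testIdx] <- 0L
  if (refitSimilarity) {
    SD <- gipKernel(aTrain, gammaPrime = config@gammaPrimeD,
                    gammaFallback = config@gammaFallback)
    SM <- gipKernel(t(aTrain), gammaPrime = config@gammaPrimeM,
                    gammaFallback = config@gammaFallback)
    SDstar <- neighborNormalize(SD, k = config@kNeighbors,
                                mode = config@neighborMode)
    SMstar <- neighborNormalize(SM, k = config@kNeighbors,
                                mode = config@neighborMode)
  } else {
    SDstar <- SDstarFull
    SMstar <- SMstarFull
  }
  bi <- bidirectionalScores(associationMatrix(aTrain), SDstar, SMstar, config)
  scores(fuseScores(bi$WLPD, bi$WLPM, beta = config@beta))
}

# Shared fold loop for LOOCV and one k-fold repeat. foldOf: integer vector
# assigning each known-pair index to a fold. Returns per-fold AUCs plus a
# per-test-pair detail table.
.runFolds <- function(a, known, foldOf, config, refitSimilarity, negPool) {
  if (!refitSimilarity) {
    SD <- gipKernel(a, gammaPrime = config@gammaPrimeD,
                    gammaFallback = config@gammaFallback)
    SM <- gipKernel(t(a), gammaPrime = config@gammaPrimeM,
                    gammaFallback = config@gammaFallback)
    SDstarFull <- neighborNormalize(SD, k = config@kNeighbors,
                                    mode = config@neighborMode)
    SMstarFull <- neighborNormalize(SM, k = config@kNeighbors,
                                    mode = config@neighborMode)
  } else SDstarFull <- SMstarFull <- NULL
  nf <- max(foldOf)
  perFold <- numeric(nf)
  det <- vector("list", nf)
  negs <- vector("list", nf)
  for (f in seq_len(nf)) {
    test <- known[foldOf == f, , drop = FALSE]
    w <- .foldScores(a, test, config, refitSimilarity, SDstarFull, SMstarFull)
    testScores <- w[test]
    negScores <- w[negPool]
    perFold[f] <- aucRank(testScores, negScores)
    negs[[f]] <- negScores
    win <- vapply(testScores,
                  function(s) mean(s > negScores) + 0.5 * mean(s == negScores),
                  numeric(1))
    det[[f]] <- data.frame(disease = rownames(a)[test[, 1L]],
                           microbe = colnames(a)[test[, 2L]],
                           fold = f, score = testScores, winFraction = win,
                           stringsAsFactors = FALSE)
  }
  list(perFold = perFold, details = do.call(rbind, det), negScores = negs)
}

#' Leave-one-out cross-validation
#'
#' Removes each known association in turn, re-runs the full pipeline on the
#' reduced matrix (by default the similarity kernels are recomputed inside
#' the fold, so the held-out edge cannot leak through the kernel), and ranks
#' the held-out pair's fused score against the negative pool: all pairs with
#' no known association in the \emph{original} matrix. The headline AUC is
#' the mean over folds of the per-pair win fraction (ties count one half);
#' `pooling = "pooled"` instead pools every fold's test and negative scores
#' into one global ranking.
#'
#' @param A an [AssociationMatrix] with at least 2 known associations and at
#'   least one unknown pair.
#' @param config an [LPConfig]. The gamma fallback is forced on during CV.
#' @param refitSimilarity recompute the kernels inside each fold (default
#'   TRUE). FALSE reproduces the leaky variant in which the full-matrix
#'   kernels are reused.
#' @param pooling `"perfold"` (mean of per-fold win fractions, default) or
#'   `"pooled"` (one global ranking).
#' @return a [CVResult].
#' @export
loocv <- function(A, config = lpConfig(), refitSimilarity = TRUE,
                  pooling = c("perfold", "pooled")) {
  pooling <- match.arg(pooling)
  config <- .cvConfig(config)
  a <- assoc(A)
  known <- which(a == 1L, arr.ind = TRUE)
  if (nrow(known) < 2L) stop("LOOCV needs at least 2 known associations")
  negPool <- which(a == 0L, arr.ind = TRUE)
  if (nrow(negPool) == 0L)
    stop("no unknown pairs: every disease-microbe pair is a known association")
  res <- .runFolds(a, known, seq_len(nrow(known)), config, refitSimilarity,
                   negPool)
  # perfold: mean over folds of the test pair's win fraction against its own
  # fold's negative pool. pooled: one global ranking of all test scores
  # against the concatenation of every fold's negative-pool scores.
  aucVal <- if (pooling == "perfold") mean(res$perFold)
            else aucRank(res$details$score, unlist(res$negScores))
  new("CVResult", protocol = "loocv", auc = aucVal,
      perFold = res$perFold, repeats = numeric(0),
      aucMean = aucVal, aucSd = NA_real_, folds = nrow(known),
      details = res$details, seed = NA_real_)
}

#' Repeated k-fold cross-validation
#'
#' Known associations are partitioned uniformly at random into `folds`
#' groups; each group's edges are zeroed simultaneously, the pipeline is
#' re-run, and the fold AUC ranks the test scores against the negative pool
#' (pairs unknown in the original matrix). The repeat AUC is the mean over
#' folds; over `repeats` repetitions the mean and sample standard deviation
#' of the repeat AUCs are reported. Fold assignment is seeded and each
#' repeat uses the deterministic stream `seed + repeat - 1`, so results are
#' exactly reproducible.
#'
#' @param A an [AssociationMatrix].
#' @param folds number of folds (>= 2, <= number of known associations).
#' @param repeats number of random re-partitions.
#' @param seed integer RNG seed.
#' @param config an [LPConfig]; gamma fallback forced on.
#' @param refitSimilarity recompute kernels inside each fold (default TRUE).
#' @return a [CVResult] whose `details` describe the first repeat.
#' @export
kfoldCV <- function(A, folds = 5L, repeats = 100L, seed = 1L,
                    config = lpConfig(), refitSimilarity = TRUE) {
  config <- .cvConfig(config)
  folds <- as.integer(folds); repeats <- as.integer(repeats)
  if (folds < 2L) stop("folds must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  a <- assoc(A)
  known <- which(a == 1L, arr.ind = TRUE)
  nKnown <- nrow(known)
  if (folds > nKnown)
    stop("folds (", folds, ") exceeds the number of known associations (",
         nKnown, ")")
  negPool <- which(a == 0L, arr.ind = TRUE)
  if (nrow(negPool) == 0L)
    stop("no unknown pairs: every disease-microbe pair is a known association")
  repAuc <- numeric(repeats)
  firstPerFold <- NULL; firstDetails <- NULL
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    foldOf <- sample(rep_len(seq_len(folds), nKnown))
    res <- .runFolds(a, known, foldOf, config, refitSimilarity, negPool)
    repAuc[r] <- mean(res$perFold)
    if (r == 1L) { firstPerFold <- res$perFold; firstDetails <- res$details }
  }
  new("CVResult", protocol = "kfold", auc = mean(repAuc),
      perFold = firstPerFold, repeats = repAuc,
      aucMean = mean(repAuc),
      aucSd = if (repeats > 1L) stats::sd(repAuc) else NA_real_,
      folds = folds, details = firstDetails, seed = as.numeric(seed))
}

#' Parameter-grid sweep
#'
#' Re-runs a full cross-validation for each value of one parameter, holding
#' everything else at the supplied configuration, and reports the AUC grid
#' together with its argmax.
#'
#' @param A an [AssociationMatrix].
#' @param param one of `"alpha"`, `"beta"`, `"kNeighbors"`.
#' @param grid numeric vector of parameter values to evaluate.
#' @param protocol `"loocv"` or `"kfold"`.
#' @param config base [LPConfig].
#' @param folds,repeats,seed passed to [kfoldCV()] when `protocol = "kfold"`.
#' @param refitSimilarity passed to the CV engine.
#' @return data.frame with columns `value` and `auc`; the attribute
#'   `"best"` holds the grid value with the highest AUC.
#' @export
parameterSweep <- function(A, param = c("alpha", "beta", "kNeighbors"),
                           grid, protocol = c("loocv", "kfold"),
                           config = lpConfig(), folds = 5L, repeats = 1L,
                           seed = 1L, refitSimilarity = TRUE) {
  param <- match.arg(param)
  protocol <- match.arg(protocol)
  if (length(grid) == 0L) stop("grid must be non-empty")
  aucs <- vapply(grid, function(v) {
    cfg <- config
    slot(cfg, param) <- if (param == "kNeighbors") as.integer(v) else v
    validObject(cfg)
    r <- if (protocol == "loocv") loocv(A, cfg, refitSimilarity)
         else kfoldCV(A, folds, repeats, seed, cfg, refitSimilarity)
    auc(r)
  }, numeric(1))
  out <- data.frame(value = grid, auc = aucs)
  attr(out, "best") <- grid[[which.max(aucs)]]
  out
}
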