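#' @include AllClasses.R
NULL

#' Label propagation on one similarity network
#'
#' Runs the label-update recursion
#' \deqn{L^k = \alpha\, S^* L^0 + (1-\alpha)\, L^{k-1}, \qquad L^0 = L_0,}
#' in which each node absorbs the propagated labels of its retained
#' neighbours with probability \eqn{\alpha} and keeps its previous label
#' with probability \eqn{1-\alpha}. Note the propagated term is built from
#' the \emph{initial} labels and is therefore constant across rounds; the
#' iterates follow the closed form
#' \eqn{L^k = (1-(1-\alpha)^k)\, S^* L^0 + (1-\alpha)^k L^0} and the
#' entry-wise L1 change between consecutive iterates decays exactly
#' geometrically with ratio \eqn{1-\alpha}. Setting `classic = TRUE`
#' switches to the classical recursion
#' \eqn{L^k = \alpha S^* L^{k-1} + (1-\alpha) L^0}.
#'
#' Iteration stops at the first round \eqn{k} whose L1 change falls below
#' `thresholdP`; the returned score sum accumulates every iterate from
#' \eqn{L^0} through the converged \eqn{L^n}.
#'
#' @param Sstar a [NormalizedKernelMatrix] (or plain matrix), n-by-n.
#' @param L0 initial label matrix with one row per network node (for the
#'   disease network, the adjacency matrix `A`; for the microbe network,
#'   `t(A)`).
#' @param alpha absorption probability in (0, 1].
#' @param thresholdP convergence threshold on the L1 change.
#' @param maxIter safety cap on the number of rounds.
#' @param classic use the classical label-propagation recursion.
#' @return a [PropagationTrace].
#' @export
propagateLabels <- function(Sstar, L0, alpha = 0.2, thresholdP = 1e-12,
                            maxIter = 1000L, classic = FALSE) {
  S <- if (is(Sstar, "NormalizedKernelMatrix")) Sstar@S else as.matrix(Sstar)
  L0 <- as.matrix(L0)
  if (nrow(L0) != nrow(S))
    stop("L0 must have one row per network node: got ", nrow(L0),
         " rows for ", nrow(S), " nodes")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (thresholdP <= 0) stop("thresholdP must be > 0")
  maxIter <- as.integer(maxIter)
  if (maxIter < 1L) stop("maxIter must be >= 1")

  source <- alpha * (S %*% L0)  # constant across rounds (non-classic form)
  Lprev <- L0
  total <- L0
  k <- 0L
  change <- Inf
  truncated <- FALSE
  repeat {
    k <- k + 1L
    Lnew <- if (classic) alpha * (S %*% Lprev) + (1 - alpha) * L0
            else source + (1 - alpha) * Lprev
    change <- sum(abs(Lnew - Lprev))
    total <- total + Lnew
    Lprev <- Lnew
    if (change < thresholdP) break
    if (k >= maxIter) {
      truncated <- TRUE
      warning("propagation did not converge within ", maxIter,
              " iterations (last L1 change ", signif(change, 3), ")")
      break
    }
  }
  dimnames(total) <- dimnames(L0)
  new("PropagationTrace", scoreSum = total, nIterations = k,
      finalChange = change, truncated = truncated)
}

#' Bidirectional propagation scores
#'
#' Runs label propagation on both similarity networks: on the disease
#' network with initial labels `A` (each disease node carries its microbe
#' association profile), and on the microbe network with initial labels
#' `t(A)`. The microbe-side score sum is transposed back to the
#' diseases-by-microbes orientation so both matrices are directly
#' comparable and fusable.
#'
#' @param A an [AssociationMatrix] (or plain 0/1 matrix).
#' @param SDstar,SMstar neighbour-normalised disease and microbe similarity
#'   matrices ([NormalizedKernelMatrix]).
#' @param config an [LPConfig]; `alpha`, `thresholdP`, `maxIter` and
#'   `classicLP` are used here.
#' @return list with elements `WLPD` and `WLPM` (both [ScoreMatrix],
#'   diseases-by-microbes) and the two [PropagationTrace]s `traceD`,
#'   `traceM`.
#' @export
bidirectionalScores <- function(A, SDstar, SMstar, config = lpConfig()) {
  a <- if (is(A, "AssociationMatrix")) assoc(A) else as.matrix(A)
  nd <- nrow(a); nm <- ncol(a)
  dimS <- function(x) nrow(if (is(x, "NormalizedKernelMatrix")) x@S else x)
  if (dimS(SDstar) != nd)
    stop("disease network has ", dimS(SDstar),
         " nodes but A has ", nd, " disease rows")
  if (dimS(SMstar) != nm)
    stop("microbe network has ", dimS(SMstar),
         " nodes but A has ", nm, " microbe columns")
  trD <- propagateLabels(SDstar, a, alpha = config@alpha,
                         thresholdP = config@thresholdP,
                         maxIter = config@maxIter, classic = config@classicLP)
  trM <- propagateLabels(SMstar, t(a), alpha = config@alpha,
                         thresholdP = config@thresholdP,
                         maxIter = config@maxIter, classic = config@classicLP)
  wlpd <- trD@scoreSum
  wlpm <- t(trM@scoreSum)
  dimnames(wlpd) <- dimnames(a)
  dimnames(wlpm) <- dimnames(a)
  list(WLPD = new("ScoreMatrix", W = wlpd),
       WLPM = new("ScoreMatrix", W = wlpm),
       traceD = trD, traceM = trM)
}

#' Fuse the two propagation score matrices
#'
#' \deqn{W = \beta\, W_{LPM} + (1-\beta)\, W_{LPD}.}
#' The fusion weight \eqn{\beta} multiplies the microbe-side matrix; to
#' weight the disease side more heavily use \eqn{\beta < 0.5} (or swap
#' \eqn{\beta \leftrightarrow 1-\beta}).
#'
#' @param WLPD,WLPM disease-side and microbe-side [ScoreMatrix] objects with
#'   identical shapes and identifier orders.
#' @param beta fusion weight in [0, 1].
#' @return the fused [ScoreMatrix].
#' @export
fuseScores <- function(WLPD, WLPM, beta = 0.75) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  wd <- if (is(WLPD, "ScoreMatrix")) scores(WLPD) else as.matrix(WLPD)
  wm <- if (is(WLPM, "ScoreMatrix")) scores(WLPM) else as.matrix(WLPM)
  if (!identical(dim(wd), dim(wm)))
    stop("score matrices have different shapes")
  if (!is.null(dimnames(wd)) && !is.null(dimnames(wm)) &&
      !identical(dimnames(wd), dimnames(wm)))
    stop("score matrices have different identifier orders")
  new("ScoreMatrix", W = beta * wm + (1 - beta) * wd)
}

#' Propagation configuration constructor
#'
#' Builds an [LPConfig] with the published default setting:
#' \eqn{\alpha = 0.2}, \eqn{\beta = 0.75}, K = 5 under the literal
#' neighbour rule, convergence threshold \eqn{P = 10^{-12}},
#' \eqn{\gamma' = 1} on both kernels.
#'
#' @param alpha absorption probability in (0, 1].
#' @param beta fusion weight in [0, 1] on the microbe-side scores.
#' @param thresholdP convergence threshold, > 0.
#' @param maxIter iteration cap.
#' @param kNeighbors neighbour-set parameter K.
#' @param neighborMode `"literal"` or `"topk"`; see [neighborNormalize()].
#' @param gammaPrimeD,gammaPrimeM raw kernel bandwidths.
#' @param gammaFallback fall back to \eqn{\gamma = \gamma'} when a profile
#'   set is entirely zero (enabled automatically inside cross-validation).
#' @param classicLP use the classical label-propagation recursion.
#' @return an [LPConfig].
#' @export
lpConfig <- function(alpha = 0.2, beta = 0.75, thresholdP = 1e-12,
                     maxIter = 1000L, kNeighbors = 5L,
                     neighborMode = c("literal", "topk"),
                     gammaPrimeD = 1, gammaPrimeM = 1,
                     gammaFallback = FALSE, classicLP = FALSE) {
  neighborMode <- match.arg(neighborMode)
  new("LPConfig", alpha = alpha, beta = beta, thresholdP = thresholdP,
      maxIter = as.integer(maxIter), kNeighbors = as.integer(kNeighbors),
      neighborMode = neighborMode, gammaPrimeD = gammaPrimeD,
      gammaPrimeM = gammaPrimeM, gammaFallback = gammaFallback,
      classicLP = classicLP)
}

#' Full prediction pipeline
#'
#' Convenience wrapper running the whole method on an association matrix:
#' GIP kernels on both axes, neighbour-restricted normalisation, label
#' propagation in both directions, and fusion of the two score matrices.
#'
#' @param A an [AssociationMatrix] (or plain 0/1 matrix).
#' @param config an [LPConfig].
#' @return the fused [ScoreMatrix] of predicted association scores.
#' @examples
#' sim <- simulateAssociations(nDiseases = 10, nMicrobes = 15, nBlocks = 2,
#'                             pIn = 0.6, pOut = 0.05, seed = 1)
#' W <- predictAssociations(sim$matrix, lpConfig(kNeighbors = 2))
#' W
#' @export
predictAssociations <- function(A, config = lpConfig()) {
  if (!is(A, "AssociationMatrix")) A <- associationMatrix(A)
  a <- assoc(A)
  SD <- gipKernel(a, gammaPrime = config@gammaPrimeD,
                  gammaFallback = config@gammaFallback)
  SM <- gipKernel(t(a), gammaPrime = config@gammaPrimeM,
                  gammaFallback = config@gammaFallback)
  SDstar <- neighborNormalize(SD, k = config@kNeighbors,
                              mode = config@neighborMode)
  SMstar <- neighborNormalize(SM, k = config@kNeighbors,
                              mode = config@neighborMode)
  bi <- bidirectionalScores(A, SDstar, SMstar, config)
  fuseScores(bi$WLPD, bi$WLPM, beta = config@beta)
}
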