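#' @import methods
NULL

#' Binary bipartite association matrix
#'
#' Wraps a diseases-by-microbes 0/1 adjacency matrix \eqn{A} together with the
#' ordered identifier lists for both axes. Row order and column order are the
#' first-appearance order of the identifiers in the input records. An entry
#' \eqn{A(i,j) = 1} records a known association between disease \eqn{i} and
#' microbe \eqn{j}; the number of ones equals the number of distinct records.
#'
#' @slot assoc integer matrix with entries in \{0, 1\}; rownames are disease
#'   identifiers, colnames are microbe identifiers.
#'
#' @seealso [buildAssociationMatrix()], [simulateAssociations()]
#' @export
setClass("AssociationMatrix", representation(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  a <- object@assoc
  msg <- character()
  if (!is.numeric(a))
    msg <- c(msg, "association matrix must be numeric")
  else if (!all(a %in% c(0, 1)))
    msg <- c(msg, "association matrix entries must be 0 or 1")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "association matrix must carry disease rownames and microbe colnames")
  else {
    if (anyDuplicated(rownames(a))) msg <- c(msg, "duplicated disease identifiers")
    if (anyDuplicated(colnames(a))) msg <- c(msg, "duplicated microbe identifiers")
  }
  if (length(msg)) msg else TRUE
})

#' Gaussian interaction profile kernel matrix
#'
#' A square symmetric similarity matrix \eqn{S} over one entity axis (diseases
#' or microbes), with \eqn{S(i,j) = \exp(-\gamma \|IP_i - IP_j\|^2)}. All
#' entries are strictly positive and the diagonal is exactly 1, so the induced
#' similarity network is fully connected.
#'
#' @slot S numeric matrix of similarities in (0, 1], dimnames = entity ids.
#' @slot gamma the bandwidth actually used, after normalisation by the mean
#'   squared profile norm.
#' @slot gammaPrime the raw bandwidth parameter supplied by the user.
#'
#' @seealso [gipKernel()]
#' @export
setClass("KernelMatrix",
         representation(S = "matrix", gamma = "numeric", gammaPrime = "numeric"))

setValidity("KernelMatrix", function(object) {
  S <- object@S
  msg <- character()
  if (nrow(S) != ncol(S)) msg <- c(msg, "kernel matrix must be square")
  if (any(S <= 0)) msg <- c(msg, "kernel entries must be strictly positive")
  if (any(S > 1 + 1e-12)) msg <- c(msg, "kernel entries must be <= 1")
  if (any(abs(diag(S) - 1) > 1e-12)) msg <- c(msg, "kernel diagonal must be 1")
  if (any(abs(S - t(S)) > 1e-12)) msg <- c(msg, "kernel matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Neighbour-restricted row-normalised similarity matrix
#'
#' The propagation weight matrix \eqn{S^*} derived from a kernel matrix: each
#' row keeps only the similarities to the nodes in its neighbour set
#' \eqn{Q_i} (which never contains the node itself) and renormalises them to
#' sum to one; entries outside \eqn{Q_i} are exactly zero.
#'
#' @slot S numeric matrix; each row sums to 1 over its retained entries.
#' @slot neighborSets list of integer vectors, one retained-column index set
#'   per row.
#' @slot mode how the neighbour sets were built: `"literal"` (drop self and
#'   the K least similar nodes) or `"topk"` (keep only the K most similar).
#' @slot k the neighbour-count parameter K.
#'
#' @seealso [neighborNormalize()]
#' @export
setClass("NormalizedKernelMatrix",
         representation(S = "matrix", neighborSets = "list",
                        mode = "character", k = "integer"))

setValidity("NormalizedKernelMatrix", function(object) {
  S <- object@S
  msg <- character()
  if (nrow(S) != ncol(S)) msg <- c(msg, "matrix must be square")
  if (length(object@neighborSets) != nrow(S))
    msg <- c(msg, "one neighbour set per row required")
  for (i in seq_len(nrow(S))) {
    q <- object@neighborSets[[i]]
    if (i %in% q) { msg <- c(msg, "neighbour sets must exclude self"); break }
    if (length(q) > 0 && abs(sum(S[i, q]) - 1) > 1e-12) {
      msg <- c(msg, "rows must sum to 1 over their neighbour set"); break
    }
    if (any(S[i, setdiff(seq_len(ncol(S)), q)] != 0)) {
      msg <- c(msg, "entries outside the neighbour set must be zero"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Label-propagation configuration
#'
#' Bundles every tunable parameter of the pipeline. The defaults reproduce
#' the published setting: absorption probability \eqn{\alpha = 0.2}, fusion
#' weight \eqn{\beta = 0.75}, K = 5 neighbours under the literal neighbour
#' rule, convergence threshold \eqn{P = 10^{-12}}, and raw kernel bandwidth
#' \eqn{\gamma' = 1} on both axes.
#'
#' @slot alpha absorption probability in (0, 1]: weight of the propagated
#'   neighbour term; 1 - alpha retains the previous label.
#' @slot beta fusion weight in [0, 1] applied to the microbe-side score
#'   matrix W_LPM (the disease-side matrix gets 1 - beta).
#' @slot thresholdP positive convergence threshold on the entry-wise L1
#'   change between consecutive label matrices.
#' @slot maxIter iteration safety cap.
#' @slot kNeighbors K, the neighbour-set size parameter.
#' @slot neighborMode `"literal"` or `"topk"` (see [neighborNormalize()]).
#' @slot gammaPrimeD,gammaPrimeM raw kernel bandwidths for the disease and
#'   microbe kernels.
#' @slot gammaFallback if TRUE, an all-zero profile matrix falls back to
#'   \eqn{\gamma = \gamma'} instead of raising an error (the cross-validation
#'   engines enable this).
#' @slot classicLP if TRUE, use the classical recursion
#'   \eqn{L^k = \alpha S^* L^{k-1} + (1-\alpha) L^0} instead of the
#'   constant-source form.
#'
#' @seealso [lpConfig()]
#' @export
setClass("LPConfig",
         representation(alpha = "numeric", beta = "numeric",
                        thresholdP = "numeric", maxIter = "integer",
                        kNeighbors = "integer", neighborMode = "character",
                        gammaPrimeD = "numeric", gammaPrimeM = "numeric",
                        gammaFallback = "logical", classicLP = "logical"))

setValidity("LPConfig", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha > 1) msg <- c(msg, "alpha must be in (0, 1]")
  if (object@beta < 0 || object@beta > 1) msg <- c(msg, "beta must be in [0, 1]")
  if (object@thresholdP <= 0) msg <- c(msg, "thresholdP must be > 0")
  if (object@maxIter < 1) msg <- c(msg, "maxIter must be >= 1")
  if (object@kNeighbors < 0) msg <- c(msg, "kNeighbors must be >= 0")
  if (!object@neighborMode %in% c("literal", "topk"))
    msg <- c(msg, "neighborMode must be 'literal' or 'topk'")
  if (object@gammaPrimeD <= 0 || object@gammaPrimeM <= 0)
    msg <- c(msg, "gamma' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Single-network propagation trace
#'
#' Result of running the label-propagation recursion on one similarity
#' network: the accumulated iterate sum (the score matrix contribution),
#' the number of update rounds performed, and the final L1 change.
#'
#' @slot scoreSum the running sum of label matrices L^0 + L^1 + ... + L^n.
#' @slot nIterations number of update rounds n at convergence (or at the cap).
#' @slot finalChange the last entry-wise L1 difference between iterates.
#' @slot truncated TRUE when the iteration cap was hit before convergence.
#'
#' @seealso [propagateLabels()]
#' @export
setClass("PropagationTrace",
         representation(scoreSum = "matrix", nIterations = "integer",
                        finalChange = "numeric", truncated = "logical"))

#' Prediction score matrix
#'
#' Dense real-valued diseases-by-microbes score matrix; larger scores mean
#' stronger predicted association. Orientation is always diseases in rows,
#' microbes in columns, matching [AssociationMatrix].
#'
#' @slot W numeric matrix with disease rownames and microbe colnames.
#'
#' @seealso [predictAssociations()], [fuseScores()]
#' @export
setClass("ScoreMatrix", representation(W = "matrix"))

setValidity("ScoreMatrix", function(object) {
  if (!all(is.finite(object@W))) "score matrix entries must be finite" else TRUE
})

#' Cross-validation result
#'
#' Holds the outcome of leave-one-out or repeated k-fold cross-validation:
#' the headline AUC, per-fold values, per-repeat AUCs with their mean and
#' sample standard deviation (k-fold only), and a per-test-pair detail table.
#'
#' @slot protocol `"loocv"` or `"kfold"`.
#' @slot auc headline AUC (mean of per-fold win fractions / fold AUCs).
#' @slot perFold per-fold AUC values of the first (or only) repeat.
#' @slot repeats per-repeat AUC means (k-fold only; length 0 for LOOCV).
#' @slot aucMean,aucSd mean and sample standard deviation across repeats.
#' @slot folds number of folds.
#' @slot details data.frame with one row per test pair of the first repeat:
#'   disease, microbe, fold, score, winFraction.
#' @slot seed RNG seed used for fold assignment (NA for LOOCV).
#' @export
setClass("CVResult",
         representation(protocol = "character", auc = "numeric",
                        perFold = "numeric", repeats = "numeric",
                        aucMean = "numeric", aucSd = "numeric",
                        folds = "integer", details = "data.frame",
                        seed = "numeric"))
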