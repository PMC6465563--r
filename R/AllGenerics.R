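#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' `diseases()` and `microbes()` return the ordered identifier lists;
#' `assoc()` the binary adjacency matrix; `scores()` the prediction score
#' matrix; `auc()` the headline cross-validation AUC.
#'
#' @param x an object of the appropriate class.
#' @return `diseases`/`microbes`: character vectors. `assoc`, `scores`:
#'   base matrices. `auc`: a single numeric value.
#' @name accessors
#' @aliases diseases microbes assoc scores auc
NULL

#' @rdname accessors
#' @export
setGeneric("diseases", function(x) standardGeneric("diseases"))

#' @rdname accessors
#' @export
setGeneric("microbes", function(x) standardGeneric("microbes"))

#' @rdname accessors
#' @export
setGeneric("assoc", function(x) standardGeneric("assoc"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setMethod("diseases", "AssociationMatrix", function(x) rownames(x@assoc))

#' @rdname accessors
#' @export
setMethod("microbes", "AssociationMatrix", function(x) colnames(x@assoc))

#' @rdname accessors
#' @export
setMethod("assoc", "AssociationMatrix", function(x) x@assoc)

#' @rdname accessors
#' @export
setMethod("diseases", "ScoreMatrix", function(x) rownames(x@W))

#' @rdname accessors
#' @export
setMethod("microbes", "ScoreMatrix", function(x) colnames(x@W))

#' @rdname accessors
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@W)

#' @rdname accessors
#' @export
setMethod("auc", "CVResult", function(x) x@auc)

#' @describeIn AssociationMatrix number of diseases (rows).
#' @param x,object an `AssociationMatrix`.
#' @export
nDiseases <- function(x) nrow(assoc(x))

#' @describeIn AssociationMatrix number of microbes (columns).
#' @export
nMicrobes <- function(x) ncol(assoc(x))

#' @describeIn AssociationMatrix number of known (1) associations.
#' @export
nAssociations <- function(x) sum(assoc(x))

#' @describeIn accessors coerce to a base matrix.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@assoc)

#' @rdname accessors
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@W)

#' @rdname accessors
#' @export
setMethod("as.matrix", "KernelMatrix", function(x, ...) x@S)

#' @rdname accessors
#' @export
setMethod("as.matrix", "NormalizedKernelMatrix", function(x, ...) x@S)

#' @rdname accessors
#' @export
setMethod("dim", "AssociationMatrix", function(x) dim(x@assoc))

#' @rdname accessors
#' @export
setMethod("dim", "ScoreMatrix", function(x) dim(x@W))

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix: %d diseases x %d microbes, %d known associations (density %.4f)\n",
              nDiseases(object), nMicrobes(object), nAssociations(object),
              mean(object@assoc)))
})

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix: %d x %d, gamma = %.6g (gamma' = %.6g)\n",
              nrow(object@S), ncol(object@S), object@gamma, object@gammaPrime))
})

setMethod("show", "NormalizedKernelMatrix", function(object) {
  cat(sprintf("NormalizedKernelMatrix: %d x %d, mode = %s, K = %d\n",
              nrow(object@S), ncol(object@S), object@mode, object@k))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d diseases x %d microbes, score range [%.4g, %.4g]\n",
              nrow(object@W), ncol(object@W), min(object@W), max(object@W)))
})

setMethod("show", "PropagationTrace", function(object) {
  cat(sprintf("PropagationTrace: %d iterations, final L1 change %.3g%s\n",
              object@nIterations, object@finalChange,
              if (object@truncated) " (truncated at maxIter)" else ""))
})

setMethod("show", "LPConfig", function(object) {
  cat(sprintf(paste0("LPConfig: alpha = %g, beta = %g, P = %g, maxIter = %d,\n",
                     "          K = %d (%s mode), gamma'_d = %g, gamma'_m = %g,",
                     " gammaFallback = %s, classicLP = %s\n"),
              object@alpha, object@beta, object@thresholdP, object@maxIter,
              object@kNeighbors, object@neighborMode,
              object@gammaPrimeD, object@gammaPrimeM,
              object@gammaFallback, object@classicLP))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s): AUC = %.4f over %d folds\n",
              object@protocol, object@auc, object@folds))
  if (length(object@repeats) > 1)
    cat(sprintf("  %d repeats: mean AUC = %.4f, sd = %.4f\n",
                length(object@repeats), object@aucMean, object@aucSd))
})
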