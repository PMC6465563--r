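#' @include AllClasses.R data-io.R
NULL

#' Simulate a bipartite association matrix with planted block structure
#'
#' Generates a sparse binary diseases-by-microbes matrix from a bipartite
#' stochastic block model: diseases and microbes are assigned to blocks
#' round-robin (so block sizes are deterministic), and a pair is associated
#' with probability `pIn` when disease and microbe blocks match and `pOut`
#' otherwise. The block ("community") structure mimics the clustering of
#' real curated association tables, so held-out edges are recoverable above
#' chance by similarity-based methods. The default shape, 40 diseases by
#' 300 microbes, mirrors the aspect ratio of the HMDAD catalogue (39 x 292)
#' so that size-asymmetry effects on the fusion weight are observable.
#'
#' @param nDiseases,nMicrobes matrix dimensions (each >= 2).
#' @param nBlocks number of planted blocks, `1 <= nBlocks <=
#'   min(nDiseases, nMicrobes)`.
#' @param pIn within-block association probability.
#' @param pOut background association probability; `0 <= pOut < pIn <= 1`.
#' @param seed integer RNG seed; output is fully deterministic given the
#'   parameters and seed.
#' @return list with elements `matrix` (an [AssociationMatrix]),
#'   `diseaseBlocks` and `microbeBlocks` (integer block labels).
#' @export
simulateAssociations <- function(nDiseases = 40L, nMicrobes = 300L,
                                 nBlocks = 5L, pIn = 0.3, pOut = 0.005,
                                 seed = 1L) {
  nDiseases <- as.integer(nDiseases); nMicrobes <- as.integer(nMicrobes)
  nBlocks <- as.integer(nBlocks)
  if (nDiseases < 2L || nMicrobes < 2L)
    stop("need at least 2 diseases and 2 microbes")
  if (nBlocks < 1L || nBlocks > min(nDiseases, nMicrobes))
    stop("nBlocks must be between 1 and min(nDiseases, nMicrobes)")
  if (pOut < 0 || pIn > 1 || pOut >= pIn)
    stop("probabilities must satisfy 0 <= pOut < pIn <= 1")
  dBlock <- (seq_len(nDiseases) - 1L) %% nBlocks + 1L
  mBlock <- (seq_len(nMicrobes) - 1L) %% nBlocks + 1L
  p <- ifelse(outer(dBlock, mBlock, "=="), pIn, pOut)
  set.seed(as.integer(seed))
  a <- matrix(as.integer(stats::runif(nDiseases * nMicrobes) < p),
              nrow = nDiseases, ncol = nMicrobes,
              dimnames = list(sprintf("disease_%03d", seq_len(nDiseases)),
                              sprintf("microbe_%03d", seq_len(nMicrobes))))
  list(matrix = new("AssociationMatrix", assoc = a),
       diseaseBlocks = dBlock, microbeBlocks = mBlock)
}

#' Shuffle the association labels, destroying block structure
#'
#' Returns a matrix with the same shape and the same number of known
#' associations, but with the 1-entries placed uniformly at random. Used as
#' the structure-free null when checking that cross-validation AUC falls to
#' chance level.
#'
#' @param A an [AssociationMatrix].
#' @param seed integer RNG seed.
#' @return an [AssociationMatrix].
#' @export
shuffleAssociations <- function(A, seed = 1L) {
  a <- assoc(A)
  set.seed(as.integer(seed))
  b <- matrix(0L, nrow(a), ncol(a), dimnames = dimnames(a))
  b[sample(length(b), sum(a))] <- 1L
  new("AssociationMatrix", assoc = b)
}

#' Hold out a random fraction of known associations
#'
#' Samples a seeded uniform subset of the known pairs, zeroes them in the
#' returned training matrix, and reports the held-out pairs for scoring.
#' The held-out count is `floor(fraction * nKnown)`.
#'
#' @param A an [AssociationMatrix] with at least 2 known associations.
#' @param fraction fraction of known pairs to hold out, in (0, 1); must
#'   yield at least one held-out pair.
#' @param seed integer RNG seed.
#' @return list with `train` (an [AssociationMatrix]) and `heldOut` (an
#'   integer matrix of row/col indices, one held-out pair per row, with
#'   `disease` and `microbe` name columns attached as a data.frame
#'   `heldOutPairs`).
#' @export
holdoutSplit <- function(A, fraction, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  a <- assoc(A)
  known <- which(a == 1L, arr.ind = TRUE)
  if (nrow(known) < 2L) stop("need at least 2 known associations to split")
  nHold <- floor(fraction * nrow(known))
  if (nHold < 1L)
    stop("fraction ", fraction, " holds out zero of ", nrow(known),
         " known pairs")
  set.seed(as.integer(seed))
  pick <- sort(sample(nrow(known), nHold))
  held <- known[pick, , drop = FALSE]
  train <- a
  train[held] <- 0L
  list(train = new("AssociationMatrix", assoc = train),
       heldOut = held,
       heldOutPairs = data.frame(disease = rownames(a)[held[, 1L]],
                                 microbe = colnames(a)[held[, 2L]],
                                 stringsAsFactors = FALSE))
}

#' Write a simulated association table to disk
#'
#' Writes the known pairs of an association matrix as a two-column TSV
#' readable by [readAssociations()], plus (optionally) a block-label
#' sidecar TSV with one row per entity.
#'
#' @param sim result of [simulateAssociations()], or an [AssociationMatrix].
#' @param path output TSV path for the association records.
#' @param blockPath optional path for the block-label sidecar.
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(sim, path, blockPath = NULL) {
  A <- if (is(sim, "AssociationMatrix")) sim else sim$matrix
  recs <- associationRecords(A)
  utils::write.table(recs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(blockPath)) {
    if (is(sim, "AssociationMatrix"))
      stop("block labels are only available from simulateAssociations() output")
    side <- rbind(
      data.frame(entity = diseases(A), axis = "disease",
                 block = sim$diseaseBlocks, stringsAsFactors = FALSE),
      data.frame(entity = microbes(A), axis = "microbe",
                 block = sim$microbeBlocks, stringsAsFactors = FALSE))
    utils::write.table(side, blockPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
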