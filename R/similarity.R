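#' @include AllClasses.R
NULL

#' Gaussian interaction profile kernel similarity
#'
#' Computes the GIP kernel over a set of binary interaction profiles: for
#' profiles \eqn{x_i} (rows of `profiles`),
#' \deqn{S(i,j) = \exp(-\gamma \|x_i - x_j\|^2), \qquad
#'       \gamma = \gamma' \Big/ \frac{1}{n}\sum_k \|x_k\|^2 .}
#' For the disease kernel pass the adjacency matrix `A` (profiles = rows);
#' for the microbe kernel pass `t(A)` (profiles = columns of `A`). The
#' bandwidth is normalised by the mean squared profile norm, i.e. by the
#' average number of known associations per entity.
#'
#' @param profiles n-by-m binary matrix, one interaction profile per row.
#' @param gammaPrime raw bandwidth \eqn{\gamma'} > 0, default 1.
#' @param gammaFallback when every profile is all-zero the normaliser is 0;
#'   with `gammaFallback = TRUE` the kernel uses \eqn{\gamma = \gamma'}
#'   instead of raising an error. Cross-validation uses the fallback, since
#'   deleting the only association of an entity can zero a whole profile set.
#' @return a [KernelMatrix]; symmetric, unit diagonal, entries in (0, 1].
#' @examples
#' S <- gipKernel(rbind(c(1, 0, 1), c(0, 1, 0)))
#' as.matrix(S)[1, 2]   # exp(-2)
#' @export
gipKernel <- function(profiles, gammaPrime = 1, gammaFallback = FALSE) {
  profiles <- as.matrix(profiles)
  if (!all(profiles %in% c(0, 1)))
    stop("interaction profiles must be binary (0/1)")
  if (gammaPrime <= 0) stop("gammaPrime must be > 0")
  n <- nrow(profiles)
  sq <- rowSums(profiles^2)
  meanSq <- mean(sq)
  if (meanSq == 0) {
    if (!gammaFallback)
      stop("all interaction profiles are all-zero: kernel bandwidth is ",
           "undefined (set gammaFallback = TRUE to use gamma = gammaPrime)")
    gamma <- gammaPrime
  } else {
    gamma <- gammaPrime / meanSq
  }
  # squared Euclidean distances via the Gram matrix; exact symmetry enforced
  G <- tcrossprod(profiles)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2 <- (D2 + t(D2)) / 2
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  S <- exp(-gamma * D2)
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  new("KernelMatrix", S = S, gamma = gamma, gammaPrime = gammaPrime)
}

# Neighbour set for row i of similarity matrix S.
# literal: all nodes except self and the K nodes LEAST similar to i.
# topk:    the K nodes MOST similar to i.
# Boundary ties broken by ascending column index.
.neighborSet <- function(S, i, k, mode) {
  others <- setdiff(seq_len(nrow(S)), i)
  if (mode == "literal") {
    if (k > length(others)) stop("K = ", k, " leaves no neighbours for n = ",
                                 nrow(S), " nodes in literal mode")
    drop <- others[order(S[i, others], others)][seq_len(k)]
    sort(setdiff(others, drop))
  } else {
    keep <- others[order(-S[i, others], others)]
    sort(keep[seq_len(min(k, length(keep)))])
  }
}

#' Neighbour-restricted row normalisation of a kernel matrix
#'
#' Builds the propagation weight matrix \eqn{S^*} from a similarity matrix:
#' each row \eqn{i} retains only its neighbour set \eqn{Q_i} and is
#' renormalised so the retained weights sum to one,
#' \deqn{S^*(i,j) = S(i,j) \big/ \sum_{k \in Q_i} S(i,k) \ \ (j \in Q_i),
#'       \qquad 0 \ \text{otherwise}.}
#' Two neighbour rules are available. The default `"literal"` rule excludes
#' the node itself and the K nodes \emph{least} similar to it, so
#' \eqn{|Q_i| = n - 1 - K}; the alternative `"topk"` rule keeps only the K
#' \emph{most} similar nodes, the usual KNN-graph construction. Both are
#' offered because the two readings differ only in which tail of the
#' similarity ranking K refers to, and published descriptions of this family
#' of methods are ambiguous between them.
#'
#' @param S a [KernelMatrix] or plain square similarity matrix with positive
#'   entries.
#' @param k neighbour-count K, `0 <= k <= n - 1`. K = 0 under `"literal"`
#'   keeps all non-self neighbours (plain row normalisation); K = 0 under
#'   `"topk"` produces empty neighbour sets (all-zero rows).
#' @param mode `"literal"` or `"topk"`.
#' @return a [NormalizedKernelMatrix].
#' @export
neighborNormalize <- function(S, k = 5L, mode = c("literal", "topk")) {
  mode <- match.arg(mode)
  Sm <- if (is(S, "KernelMatrix")) S@S else as.matrix(S)
  n <- nrow(Sm)
  if (n != ncol(Sm)) stop("similarity matrix must be square")
  k <- as.integer(k)
  if (k < 0) stop("K must be >= 0")
  if (k > n - 1L)
    stop("K = ", k, " exceeds the number of potential neighbours (n - 1 = ",
         n - 1L, ")")
  Sstar <- matrix(0, n, n, dimnames = dimnames(Sm))
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    q <- .neighborSet(Sm, i, k, mode)
    sets[[i]] <- q
    if (length(q) > 0)
      Sstar[i, q] <- Sm[i, q] / sum(Sm[i, q])
  }
  new("NormalizedKernelMatrix", S = Sstar, neighborSets = sets,
      mode = mode, k = k)
}
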