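#' @include AllClasses.R
NULL

# Normalisation key: trim, collapse internal whitespace, case-fold.
# Display names keep the first-seen casing (trimmed/collapsed).
.normKey <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))
.normDisplay <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Read disease-microbe association records from a delimited text file
#'
#' Reads one association record per line from a tab-separated (or otherwise
#' delimited) export such as a local HMDAD download. The reader preserves
#' file order and does not deduplicate; collapsing duplicates is the job of
#' [buildAssociationMatrix()].
#'
#' @param path path to the text file.
#' @param sep field separator, default tab.
#' @param header logical; if TRUE the first line is a header. When the
#'   column selectors are character they are matched against the header.
#' @param diseaseCol,microbeCol column index (or name, with `header = TRUE`)
#'   of the disease and microbe fields.
#' @return a data.frame with character columns `disease` and `microbe`, one
#'   row per record, whitespace-trimmed, in file order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("asthma\tClostridium difficile", "asthma\tFirmicutes"), tf)
#' readAssociations(tf)
#' @export
readAssociations <- function(path, sep = "\t", header = FALSE,
                             diseaseCol = 1L, microbeCol = 2L) {
  if (!file.exists(path))
    stop("association file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineNo <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineNo <- lineNo[keep]
  if (header) {
    if (length(lines) == 0L) stop("file has no header line: ", path)
    hdr <- trimws(strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]])
    resolve <- function(col, what) {
      if (is.character(col)) {
        i <- match(col, hdr)
        if (is.na(i)) stop("no column named '", col, "' for ", what,
                           " in header of ", path)
        i
      } else as.integer(col)
    }
    diseaseCol <- resolve(diseaseCol, "disease")
    microbeCol <- resolve(microbeCol, "microbe")
    lines <- lines[-1L]; lineNo <- lineNo[-1L]
  } else {
    diseaseCol <- as.integer(diseaseCol)
    microbeCol <- as.integer(microbeCol)
  }
  need <- max(diseaseCol, microbeCol)
  fields <- strsplit(lines, sep, fixed = TRUE)
  d <- character(length(fields)); m <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < need)
      stop("malformed line ", lineNo[i], " in ", path,
           ": expected at least ", need, " fields, found ", length(f))
    d[i] <- trimws(f[[diseaseCol]])
    m[i] <- trimws(f[[microbeCol]])
    if (!nzchar(d[i]) || !nzchar(m[i]))
      stop("malformed line ", lineNo[i], " in ", path,
           ": empty disease or microbe identifier")
  }
  data.frame(disease = d, microbe = m, stringsAsFactors = FALSE)
}

#' Build the binary association matrix from records
#'
#' Collapses duplicate records (case-insensitively, after whitespace
#' normalisation) and assembles the diseases-by-microbes 0/1 adjacency
#' matrix. Identifier order is first appearance in the record list, and the
#' first-seen casing of each identifier is kept for display.
#'
#' @param records a data.frame with columns `disease` and `microbe` (as
#'   returned by [readAssociations()]), or a 2-column character matrix.
#' @return an [AssociationMatrix].
#' @examples
#' recs <- data.frame(disease = c("d1", "d1", "d1", "d2"),
#'                    microbe = c("m1", "m1", "m2", "m1"))
#' buildAssociationMatrix(recs)   # 2 x 2, three ones
#' @export
buildAssociationMatrix <- function(records) {
  if (is.matrix(records))
    records <- data.frame(disease = records[, 1L], microbe = records[, 2L],
                          stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    stop("cannot build an association matrix from zero records")
  dKey <- .normKey(records$disease)
  mKey <- .normKey(records$microbe)
  if (any(!nzchar(dKey)) || any(!nzchar(mKey)))
    stop("empty identifier in records")
  dLevels <- unique(dKey)
  mLevels <- unique(mKey)
  dNames <- .normDisplay(records$disease)[match(dLevels, dKey)]
  mNames <- .normDisplay(records$microbe)[match(mLevels, mKey)]
  a <- matrix(0L, nrow = length(dLevels), ncol = length(mLevels),
              dimnames = list(dNames, mNames))
  a[cbind(match(dKey, dLevels), match(mKey, mLevels))] <- 1L
  new("AssociationMatrix", assoc = a)
}

#' Construct an AssociationMatrix from a plain 0/1 matrix
#'
#' @param a a numeric matrix with entries in \{0,1\}. Missing dimnames are
#'   filled with generated identifiers.
#' @return an [AssociationMatrix].
#' @export
associationMatrix <- function(a) {
  a <- as.matrix(a)
  if (is.null(rownames(a)))
    rownames(a) <- sprintf("disease_%03d", seq_len(nrow(a)))
  if (is.null(colnames(a)))
    colnames(a) <- sprintf("microbe_%03d", seq_len(ncol(a)))
  storage.mode(a) <- "integer"
  new("AssociationMatrix", assoc = a)
}

#' Top-ranked candidate associations per disease
#'
#' For each disease, ranks microbes by descending prediction score and
#' returns the top `topK`. With `knownFilter = TRUE` (the default, and the
#' usual use case: proposing new associations) pairs already known in `A`
#' are excluded before ranking. Ties are broken by ascending column index,
#' so output is fully deterministic.
#'
#' @param W a [ScoreMatrix] (or plain matrix) of prediction scores.
#' @param A the [AssociationMatrix] of known pairs; required when
#'   `knownFilter` is TRUE.
#' @param topK maximum number of microbes listed per disease; fewer are
#'   emitted when fewer candidates exist.
#' @param knownFilter exclude known pairs from the ranking.
#' @return data.frame with columns `disease`, `rank`, `microbe`, `score`.
#' @export
topAssociations <- function(W, A = NULL, topK = 10L, knownFilter = TRUE) {
  if (topK < 1L) stop("topK must be >= 1")
  w <- if (is(W, "ScoreMatrix")) scores(W) else as.matrix(W)
  mask <- NULL
  if (knownFilter) {
    if (is.null(A)) stop("knownFilter = TRUE requires the association matrix A")
    a <- if (is(A, "AssociationMatrix")) assoc(A) else as.matrix(A)
    if (!identical(dim(a), dim(w)))
      stop("score matrix (", nrow(w), "x", ncol(w),
           ") and association matrix (", nrow(a), "x", ncol(a),
           ") dimensions differ")
    mask <- a == 1
  }
  out <- vector("list", nrow(w))
  for (i in seq_len(nrow(w))) {
    cand <- seq_len(ncol(w))
    if (!is.null(mask)) cand <- cand[!mask[i, ]]
    if (length(cand) == 0L) next
    ord <- cand[order(-w[i, cand], cand)]
    ord <- ord[seq_len(min(topK, length(ord)))]
    out[[i]] <- data.frame(disease = rownames(w)[i],
                           rank = seq_along(ord),
                           microbe = colnames(w)[ord],
                           score = w[i, ord],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(disease = character(), rank = integer(),
                      microbe = character(), score = numeric())
  rownames(res) <- NULL
  res
}

#' Write ranked predictions to a tab-separated file
#'
#' Convenience wrapper around [topAssociations()] that writes the ranking
#' table as TSV (columns disease, rank, microbe, score).
#'
#' @inheritParams topAssociations
#' @param path output file path.
#' @return the ranking data.frame, invisibly.
#' @export
writeRankings <- function(W, A = NULL, path, topK = 10L, knownFilter = TRUE) {
  tab <- topAssociations(W, A, topK = topK, knownFilter = knownFilter)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Recover the distinct record list from an association matrix
#'
#' Inverse of [buildAssociationMatrix()] up to deduplication: returns one
#' record per 1-entry, in row-major order.
#'
#' @param A an [AssociationMatrix].
#' @return data.frame with columns `disease` and `microbe`.
#' @export
associationRecords <- function(A) {
  a <- assoc(A)
  idx <- which(t(a) == 1L)  # row-major traversal
  j <- (idx - 1L) %% ncol(a) + 1L
  i <- (idx - 1L) %/% ncol(a) + 1L
  data.frame(disease = rownames(a)[i], microbe = colnames(a)[j],
             stringsAsFactors = FALSE)
}
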