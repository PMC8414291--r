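## SimilarityMatrix construction, accessors, and matrix-level
## combination.

#' Status codes of similarity-matrix pairs
#'
#' @return Named integer vector mapping status names
#'   (\code{uncomputed}, \code{computed}, \code{skipped_positive},
#'   \code{skipped_negative}) to the codes stored in the status matrix.
#' @export
statusCodes <- function() {
  c(uncomputed = 0L, computed = 1L,
    skipped_positive = 2L, skipped_negative = 3L)
}

#' Create a SimilarityMatrix
#'
#' @param sourceIds,targetIds Ordered element identifier vectors.
#' @param values Optional numeric matrix (defaults to all zeros).
#' @param status Optional integer status matrix (defaults to
#'   uncomputed).
#' @return A [SimilarityMatrix-class].
#' @export
similarityMatrix <- function(sourceIds, targetIds, values = NULL,
                             status = NULL) {
  n1 <- length(sourceIds); n2 <- length(targetIds)
  if (is.null(values))
    values <- matrix(0, n1, n2)
  if (is.null(status))
    status <- matrix(statusCodes()[["computed"]], n1, n2)
  dimnames(values) <- dimnames(status) <- list(sourceIds, targetIds)
  storage.mode(status) <- "integer"
  methods::new("SimilarityMatrix", sourceIds = sourceIds,
               targetIds = targetIds, values = values, status = status)
}

#' @rdname SimilarityMatrix-class
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) {
  v <- x@values
  v[x@status != statusCodes()[["computed"]]] <- 0
  v
})

#' @rdname SimilarityMatrix-class
#' @export
setMethod("pairStatus", "SimilarityMatrix", function(x) x@status)

setMethod("show", "SimilarityMatrix", function(object) {
  st <- object@status
  codes <- statusCodes()
  cat(sprintf("SimilarityMatrix: %d x %d pairs\n",
              length(object@sourceIds), length(object@targetIds)))
  cat(sprintf("  computed %d, skipped positive %d, skipped negative %d, uncomputed %d\n",
              sum(st == codes[["computed"]]),
              sum(st == codes[["skipped_positive"]]),
              sum(st == codes[["skipped_negative"]]),
              sum(st == codes[["uncomputed"]])))
})

#' Combine similarity matrices with normalized weights
#'
#' Computes the weighted average \code{S = sum_d w_d * S_d} with the
#' weights normalized to sum to one. A pair skipped in every input stays
#' skipped (with the skip kind of the first input recording it); a pair
#' computed in any input is computed in the output, with skipped inputs
#' contributing similarity 0.
#'
#' @param mats Named list of [SimilarityMatrix-class] objects over the
#'   same source/target identifier spaces.
#' @param weights Numeric weights, one per matrix (matched by name when
#'   both are named); all non-negative, positive sum.
#' @return A [SimilarityMatrix-class].
#' @export
combineMatrices <- function(mats, weights = NULL) {
  stopifnot(length(mats) > 0)
  if (is.null(weights)) weights <- rep(1, length(mats))
  if (!is.null(names(weights)) && !is.null(names(mats)))
    weights <- weights[names(mats)]
  if (length(weights) != length(mats))
    stop("need one weight per matrix", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) <= 0) stop("weight sum must be > 0", call. = FALSE)
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (!identical(m@sourceIds, ref@sourceIds) ||
        !identical(m@targetIds, ref@targetIds))
      stop("similarity matrices have mismatched index spaces",
           call. = FALSE)
  }
  w <- weights / sum(weights)
  codes <- statusCodes()
  acc <- matrix(0, length(ref@sourceIds), length(ref@targetIds))
  anyComputed <- matrix(FALSE, nrow(acc), ncol(acc))
  for (k in seq_along(mats)) {
    acc <- acc + w[k] * similarityValues(mats[[k]])
    anyComputed <- anyComputed | (mats[[k]]@status == codes[["computed"]])
  }
  status <- ref@status
  status[anyComputed] <- codes[["computed"]]
  # pairs computed nowhere keep the first matrix's skip/uncomputed mark
  similarityMatrix(ref@sourceIds, ref@targetIds,
                   values = pmin(pmax(acc, 0), 1), status = status)
}
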