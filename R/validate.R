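#' Validate a P-value matrix, direction matrix and constraints vector
#'
#' Checks and normalises the three inputs of a directional merging analysis:
#' a genes-by-datasets matrix of P-values, a same-shaped matrix of observed
#' direction signs, and a per-dataset constraints vector (CV) of expected
#' directions. P-values are clamped into \code{[1e-300, 1]} so their
#' logarithms are finite, direction entries are reduced to unit signs, and
#' any nonzero direction in a directionless dataset (CV entry 0) is coerced
#' to 0 with a warning, since such datasets contribute evidence through
#' P-values only.
#'
#' @param scores Numeric matrix of P-values in (0, 1], with unique row names
#'   (gene identifiers) and column names (dataset identifiers).
#' @param directions Numeric matrix of the same shape and dimnames as
#'   \code{scores} holding observed direction signs; any numeric effect size
#'   (log fold-change, log hazard ratio, correlation) is reduced to its sign.
#'   \code{NULL} means no directional information (all zeros).
#' @param cv Numeric vector of expected per-dataset directions, each in
#'   \{-1, 0, +1\}, aligned with the columns of \code{scores}. A dataset is
#'   directionless iff its CV entry is 0. \code{NULL} means all zeros.
#'
#' @return A list with elements \code{scores}, \code{directions} and
#'   \code{cv}, normalised as described.
#' @examples
#' p <- matrix(c(0.01, 0.5, 0.2, 1, 0.03, 0.9), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("rna", "protein")))
#' d <- matrix(c(1, -1, 1, 0, 1, -1), nrow = 3, dimnames = dimnames(p))
#' v <- validate_inputs(p, d, cv = c(1, 1))
#' @export
validate_inputs <- function(scores, directions = NULL, cv = NULL) {
  scores <- as_score_matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)

  if (is.null(directions)) {
    directions <- array(0, dim(scores), dimnames = dimnames(scores))
  } else {
    if (!is.matrix(directions) && !is.data.frame(directions))
      stop("'directions' must be a matrix", call. = FALSE)
    directions <- as.matrix(directions)
    if (!identical(dim(directions), dim(scores)))
      stop("'directions' must have the same shape as 'scores'", call. = FALSE)
    if (!is.null(dimnames(directions)) &&
        (!identical(rownames(directions), rownames(scores)) ||
         !identical(colnames(directions), colnames(scores))))
      stop("'directions' row/column names must match 'scores'", call. = FALSE)
    if (!is.numeric(directions))
      stop("'directions' must be numeric", call. = FALSE)
    directions[is.na(directions)] <- 0
    directions <- sign(directions)
    dimnames(directions) <- dimnames(scores)
  }

  if (is.null(cv)) cv <- rep(0, k)
  if (!is.numeric(cv))
    stop("constraints vector must be numeric", call. = FALSE)
  if (length(cv) != k)
    stop(sprintf("constraints vector has length %d but there are %d datasets",
                 length(cv), k), call. = FALSE)
  if (anyNA(cv)) stop("constraints vector contains NA", call. = FALSE)
  cv <- sign(cv)
  names(cv) <- colnames(scores)

  # directionless datasets carry no sign information
  zero_cols <- which(cv == 0)
  if (length(zero_cols)) {
    bad <- directions[, zero_cols, drop = FALSE] != 0
    if (any(bad)) {
      warning(sprintf(
        "%d nonzero direction(s) in directionless dataset(s) coerced to 0",
        sum(bad)), call. = FALSE)
      directions[, zero_cols][bad] <- 0
    }
  }

  list(scores = scores, directions = directions, cv = cv)
}

# Normalise a P-value matrix: numeric, in (0, 1] after clamping, unique
# dimnames. Values below 1e-300 (including 0) are clamped so log() is finite;
# missing cells take the no-evidence value P = 1.
as_score_matrix <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores)) stop("'scores' must be a matrix", call. = FALSE)
  if (!is.numeric(scores)) stop("'scores' must be numeric", call. = FALSE)
  if (nrow(scores) < 1L || ncol(scores) < 1L)
    stop("'scores' must have at least one gene and one dataset", call. = FALSE)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("gene", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("dataset", seq_len(ncol(scores)))
  if (anyDuplicated(rownames(scores)))
    stop("duplicate gene identifiers in 'scores'", call. = FALSE)
  if (anyDuplicated(colnames(scores)))
    stop("duplicate dataset identifiers in 'scores'", call. = FALSE)
  scores[is.na(scores)] <- 1
  if (any(scores < 0)) stop("P-values must be non-negative", call. = FALSE)
  if (any(scores > 1)) stop("P-values must not exceed 1", call. = FALSE)
  n_clamped <- sum(scores < 1e-300)
  if (n_clamped > 0) {
    message(sprintf("clamped %d P-value(s) below 1e-300", n_clamped))
    scores[scores < 1e-300] <- 1e-300
  }
  scores
}
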