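#' One-hot encoding of DNA windows
#'
#' Each base is represented as a binary indicator vector of length 4 under the
#' fixed alphabet order A, C, G, T. A window of length L becomes an L x 4
#' binary matrix whose rows each sum to 1, the encoding used by the numeric
#' models (RBF-kernel SVM after flattening, neural networks as an L x 4
#' channel matrix).
#'
#' @param sequence A single character string over A, C, G, T
#'   (case-insensitive; soft-masked lowercase input is uppercased).
#' @return An integer matrix of dimension `nchar(sequence)` x 4 with column
#'   names A, C, G, T; every row sums to exactly 1.
#' @examples
#' one_hot("ACGT")        # the 4 x 4 identity matrix
#' one_hot_decode(one_hot("GATTACA"))
#' @export
one_hot <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_ALPHABET)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1L]
    stop(sprintf("cannot one-hot encode character '%s' at position %d (alphabet is A,C,G,T)",
                 chars[pos], pos), call. = FALSE)
  }
  m <- matrix(0L, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, DNA_ALPHABET))
  if (length(chars) > 0L) m[cbind(seq_along(idx), idx)] <- 1L
  m
}

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot()]: the encoding is a bijection over sequences in
#' \{A,C,G,T\}^L.
#'
#' @param matrix A binary matrix with 4 columns and one 1 per row.
#' @return A character string.
#' @export
one_hot_decode <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 4L)
  if (nrow(matrix) == 0L) return("")
  if (!all(rowSums(matrix) == 1) || !all(matrix %in% c(0, 1))) {
    stop("not a valid one-hot matrix: each row must contain a single 1", call. = FALSE)
  }
  paste(DNA_ALPHABET[max.col(matrix)], collapse = "")
}

#' Flatten a one-hot matrix to a feature vector
#'
#' Row-major flattening: base i occupies entries 4(i-1)+1 .. 4i. A
#' 1,003-base window yields 4,012 features; the entries sum to the window
#' length (one hot bit per base).
#'
#' @param matrix A one-hot matrix as produced by [one_hot()].
#' @return A numeric vector of length `4 * nrow(matrix)`.
#' @export
flatten_one_hot <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 4L)
  as.numeric(t(matrix))
}

#' One-hot encode a set of equal-length sequences as a 3D array
#'
#' Convenience encoder for the neural models: returns an array of dimension
#' (n, L, 4) with the alphabet on the channel axis.
#'
#' @param sequences Character vector of equal-length DNA strings.
#' @return A numeric array of dimension `c(length(sequences), L, 4)`.
#' @export
one_hot_array <- function(sequences) {
  n <- length(sequences)
  if (n == 0L) stop("no sequences to encode", call. = FALSE)
  L <- nchar(sequences[1L])
  if (!all(nchar(sequences) == L)) stop("sequences must have equal length", call. = FALSE)
  out <- array(0, dim = c(n, L, 4L))
  for (i in seq_len(n)) out[i, , ] <- one_hot(sequences[i])
  out
}

#' Flatten a set of sequences into a numeric design matrix
#'
#' One row per sequence, `4 * L` columns (row-major per-base one-hot blocks);
#' the representation used by the RBF-kernel SVM.
#'
#' @param sequences Character vector of equal-length DNA strings.
#' @return A numeric matrix of dimension `length(sequences)` x `4 * L`.
#' @export
one_hot_matrix <- function(sequences) {
  n <- length(sequences)
  if (n == 0L) stop("no sequences to encode", call. = FALSE)
  L <- nchar(sequences[1L])
  if (!all(nchar(sequences) == L)) stop("sequences must have equal length", call. = FALSE)
  out <- matrix(0, nrow = n, ncol = 4L * L)
  for (i in seq_len(n)) out[i, ] <- flatten_one_hot(one_hot(sequences[i]))
  out
}
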