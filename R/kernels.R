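#' Weighted-degree kernel weights
#'
#' The weight of k-mer length k in the weighted-degree string kernel is
#' `beta_k = 2 (d - k + 1) / (d (d + 1))`. The weights are strictly
#' decreasing in k and sum to 1 for every d.
#'
#' @param d Maximum k-mer length (positive integer).
#' @return Numeric vector `beta[1..d]`.
#' @export
wd_beta <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != floor(d)) {
    stop("d must be a positive integer", call. = FALSE)
  }
  k <- seq_len(d)
  2 * (d - k + 1) / (d * (d + 1))
}

#' Weighted-degree kernel parameters
#'
#' @param d Maximum k-mer length; default 10 (the value that trades accuracy
#'   against gram-matrix cost well for 1,003-base TSS windows).
#' @return List of class `wd_kernel_params` with `d` and `beta`.
#' @export
wd_kernel_params <- function(d = 10L) {
  structure(list(d = as.integer(d), beta = wd_beta(d)), class = "wd_kernel_params")
}

#' RBF kernel parameters
#'
#' @param gamma Positive bandwidth; larger values localize the influence of
#'   each support vector.
#' @return List of class `rbf_kernel_params`.
#' @export
rbf_kernel_params <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive real", call. = FALSE)
  }
  structure(list(gamma = gamma), class = "rbf_kernel_params")
}

# Map a character vector of equal-length DNA strings to an integer matrix
# (one row per sequence, bases coded 1..4). Comparison on small integers is
# contractually identical to character comparison.
seqs_to_int <- function(seqs) {
  L <- nchar(seqs[1L])
  if (!all(nchar(seqs) == L)) stop("sequences must have equal length", call. = FALSE)
  m <- matrix(match(unlist(strsplit(toupper(seqs), "", fixed = TRUE)), DNA_ALPHABET),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("sequences contain characters outside A,C,G,T", call. = FALSE)
  m
}

# Contribution of a maximal run of r consecutive positional base matches:
# it contains max(0, r - k + 1) matching k-mers for each k <= d, so the run
# contributes sum_{k=1}^{min(r,d)} beta_k (r - k + 1). Precomputing this per
# run length turns each kernel evaluation into a single rle() pass.
wd_run_weights <- function(L, params) {
  vapply(seq_len(L), function(r) {
    k <- seq_len(min(r, params$d))
    sum(params$beta[k] * (r - k + 1))
  }, numeric(1))
}

#' Weighted-degree string kernel between two sequences
#'
#' Scores two equal-length sequences by their positionally matching k-mers:
#' `K(s, t) = sum_{k=1}^{d} beta_k sum_{l=1}^{L-k+1} I(u_{k,l}(s) = u_{k,l}(t))`
#' where `u_{k,l}` is the k-mer starting at position l. Positional (no-shift)
#' variant; symmetric in its arguments.
#'
#' @param s_i,s_j Equal-length DNA strings.
#' @param params A `wd_kernel_params` object.
#' @return Kernel value (non-negative real).
#' @export
wd_kernel <- function(s_i, s_j, params = wd_kernel_params()) {
  if (nchar(s_i) != nchar(s_j)) stop("sequences must have equal length", call. = FALSE)
  m <- seqs_to_int(c(s_i, s_j))
  w <- wd_run_weights(ncol(m), params)
  r <- rle(m[1L, ] == m[2L, ])
  sum(w[r$lengths[r$values]])
}

#' Brute-force weighted-degree kernel (reference oracle)
#'
#' Transparent double loop over every k-mer length and start position,
#' comparing substrings directly. Quadratic in window length times d; used
#' to validate the optimized implementation.
#'
#' @inheritParams wd_kernel
#' @return Kernel value, identical to [wd_kernel()] up to 1e-9.
#' @export
wd_kernel_naive <- function(s_i, s_j, params = wd_kernel_params()) {
  L <- nchar(s_i)
  if (nchar(s_j) != L) stop("sequences must have equal length", call. = FALSE)
  s_i <- toupper(s_i); s_j <- toupper(s_j)
  total <- 0
  for (k in seq_len(params$d)) {
    if (k > L) break
    matches <- 0L
    for (l in seq_len(L - k + 1L)) {
      if (substr(s_i, l, l + k - 1L) == substr(s_j, l, l + k - 1L)) {
        matches <- matches + 1L
      }
    }
    total <- total + params$beta[k] * matches
  }
  total
}

#' Weighted-degree gram matrix
#'
#' Pairwise kernel values for two sequence lists. When `seqs_cols` is `NULL`
#' the self-gram is computed once per unordered pair and mirrored, so the
#' result is exactly symmetric. Rows may be processed in blocks (the result
#' is bit-identical regardless of `n_blocks`, which only controls the work
#' decomposition).
#'
#' @param seqs_rows,seqs_cols Character vectors of equal-length sequences;
#'   `seqs_cols = NULL` computes the symmetric self-gram of `seqs_rows`.
#' @param params A `wd_kernel_params`.
#' @param n_blocks Number of row blocks to decompose the computation into.
#' @return Numeric matrix `length(seqs_rows)` x `length(seqs_cols)`.
#' @export
wd_gram <- function(seqs_rows, seqs_cols = NULL, params = wd_kernel_params(),
                    n_blocks = 1L) {
  self <- is.null(seqs_cols)
  if (self) seqs_cols <- seqs_rows
  A <- seqs_to_int(seqs_rows)
  B <- seqs_to_int(seqs_cols)
  if (ncol(A) != ncol(B)) stop("row and column sequences must have equal length", call. = FALSE)
  L <- ncol(A)
  w <- wd_run_weights(L, params)
  n <- nrow(A); m <- nrow(B)
  K <- matrix(0, n, m)
  pair_value <- function(a, b) {
    r <- rle(a == b)
    sum(w[r$lengths[r$values]])
  }
  nb <- max(1L, min(as.integer(n_blocks), n))
  blocks <- split(seq_len(n), ceiling(seq_len(n) * nb / n))
  for (blk in blocks) {
    for (i in blk) {
      js <- if (self) i:m else seq_len(m)
      for (j in js) {
        v <- pair_value(A[i, ], B[j, ])
        K[i, j] <- v
        if (self) K[j, i] <- v
      }
    }
  }
  K
}

#' RBF (Gaussian) kernel between two numeric vectors
#'
#' `K(x, x') = exp(-gamma * ||x - x'||^2)`; value in (0, 1], equal to 1 iff
#' the vectors coincide.
#'
#' @param x,x_prime Equal-length numeric vectors.
#' @param params An `rbf_kernel_params`.
#' @return Kernel value.
#' @export
rbf_kernel <- function(x, x_prime, params) {
  if (length(x) != length(x_prime)) stop("vectors must have equal length", call. = FALSE)
  exp(-params$gamma * sum((x - x_prime)^2))
}

#' RBF gram matrix
#'
#' @param X,Y Numeric matrices (rows = instances); `Y = NULL` for the
#'   self-gram.
#' @param params An `rbf_kernel_params`.
#' @return Matrix of kernel values.
#' @export
rbf_gram <- function(X, Y = NULL, params) {
  if (is.null(Y)) Y <- X
  if (ncol(X) != ncol(Y)) stop("feature dimensions differ", call. = FALSE)
  rx <- rowSums(X^2)
  ry <- rowSums(Y^2)
  d2 <- outer(rx, ry, "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0  # numerical negatives from cancellation
  K <- exp(-params$gamma * d2)
  if (identical(dim(X), dim(Y))) K[abs(d2) < 1e-12 & row(K) == col(K)] <- 1
  K
}

#' Cache a gram matrix on disk
#'
#' Stores the dense matrix as a flat binary array of doubles plus a JSON
#' header carrying the kernel degree and a hash of the sequence list, so
#' expensive gram computations are resumable across runs.
#'
#' @param K Gram matrix.
#' @param path File path for the binary payload; the header is written to
#'   `<path>.json`.
#' @param d Kernel degree recorded in the header.
#' @param seqs The sequence list the matrix was computed from (hashed).
#' @return `path`, invisibly.
#' @export
wd_gram_cache_write <- function(K, path, d, seqs) {
  header <- list(d = d, nrow = nrow(K), ncol = ncol(K),
                 seq_hash = sequence_list_hash(seqs))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(K), con)
  invisible(path)
}

#' Read a cached gram matrix, validating its header
#'
#' @param path Path used in [wd_gram_cache_write()].
#' @param d Expected kernel degree.
#' @param seqs Expected sequence list (hash must match).
#' @return The gram matrix, or `NULL` when the cache is absent or stale.
#' @export
wd_gram_cache_read <- function(path, d, seqs) {
  hdr_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(hdr_path)) return(NULL)
  header <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  if (!identical(as.integer(header$d), as.integer(d)) ||
      !identical(header$seq_hash, sequence_list_hash(seqs))) {
    return(NULL)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = header$nrow * header$ncol)
  matrix(vals, nrow = header$nrow, ncol = header$ncol)
}

# Order-sensitive polynomial hash of a sequence list (hex string). Arithmetic
# kept below 2^31 so it stays exact in doubles on every platform.
sequence_list_hash <- function(seqs) {
  mod <- 2147483647
  h <- 17
  for (s in seqs) {
    for (v in c(utf8ToInt(s), 10L)) {  # 10 = record separator
      h <- (h * 31 + v) %% mod
    }
  }
  sprintf("%08x", as.integer(h))
}
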