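#' Tanimoto coefficient between two binary fingerprints
#'
#' Computes the set-overlap similarity `|A n B| / (|A| + |B| - |A n B|)`
#' between two fixed-length binary fingerprints, the standard similarity
#' measure for hashed circular substructure fingerprints such as ECFP4.
#'
#' @param a,b Binary vectors (0/1, logical, or integer) of equal length.
#' @return Similarity in `[0, 1]`; 1 if and only if the bit sets are
#'   identical (and non-empty).
#' @examples
#' a <- c(1, 1, 0, 0, 1, 0)
#' b <- c(1, 0, 0, 1, 1, 0)
#' tanimoto(a, b)
#' @seealso [tanimoto_distance()], [pairwise_distance_matrix()]
#' @export
tanimoto <- function(a, b) {
  a <- as_fp_bits(a)
  b <- as_fp_bits(b)
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  inter <- sum(a & b)
  union <- sum(a) + sum(b) - inter
  if (union == 0L) {
    stop("Tanimoto undefined: both fingerprints are all-zero")
  }
  inter / union
}

#' Tanimoto distance between two fingerprints
#'
#' The complement `1 - Tc(a, b)`; zero if and only if the two bit sets
#' are identical.
#'
#' @inheritParams tanimoto
#' @return Distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto(a, b)

#' Pairwise Tanimoto similarity matrix for a fingerprint set
#'
#' @param fps Integer 0/1 matrix, one fingerprint per row.
#' @return Symmetric `n x n` similarity matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  fps <- as_fp_matrix(fps)
  pop <- rowSums(fps)
  if (any(pop == 0L)) {
    stop("all-zero fingerprint(s) at row(s): ",
         paste(which(pop == 0L), collapse = ", "))
  }
  inter <- tcrossprod(fps)
  union <- outer(pop, pop, "+") - inter
  tc <- inter / union
  dimnames(tc) <- list(rownames(fps), rownames(fps))
  tc
}

#' Pairwise Tanimoto distance matrix
#'
#' Distance matrix `1 - Tc` over all compound pairs of an activity class
#' (or a raw fingerprint matrix); this is the dissimilarity that both the
#' multidimensional-scaling and the Neuroscale embeddings preserve.
#'
#' @param x An [activity_class()] or a 0/1 fingerprint matrix.
#' @return Symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
pairwise_distance_matrix <- function(x) {
  fps <- if (is_activity_class(x)) x$fps else x
  fps <- as_fp_matrix(fps)
  if (nrow(fps) == 1L) {
    d <- matrix(0, 1, 1)
    dimnames(d) <- list(rownames(fps), rownames(fps))
    return(d)
  }
  d <- 1 - tanimoto_matrix(fps)
  diag(d) <- 0
  d
}

# ---- serialization ---------------------------------------------------------

#' Serialize a fingerprint as a '0'/'1' bit string
#' @param bits Binary vector.
#' @return Single string, first bit first.
#' @export
fp_to_bitstring <- function(bits) {
  paste(as.integer(as_fp_bits(bits)), collapse = "")
}

#' Parse a '0'/'1' bit string into a binary vector
#' @param s Single string of `0`/`1` characters.
#' @return Integer 0/1 vector.
#' @export
fp_from_bitstring <- function(s) {
  v <- as.integer(strsplit(s, "", fixed = TRUE)[[1]])
  if (anyNA(v) || any(v > 1L)) stop("bit string may contain only '0' and '1'")
  v
}

#' Serialize a fingerprint as hexadecimal
#'
#' Bits are grouped into nibbles of four in fingerprint order; within each
#' nibble the first fingerprint bit is the most significant bit of the hex
#' digit (most-significant-first convention). The length must be a
#' multiple of 4.
#'
#' @param bits Binary vector whose length is a multiple of 4.
#' @return Lower-case hexadecimal string of `length(bits) / 4` digits.
#' @export
fp_to_hex <- function(bits) {
  bits <- as.integer(as_fp_bits(bits))
  if (length(bits) %% 4L != 0L) {
    stop("hex serialization requires a fingerprint length divisible by 4")
  }
  m <- matrix(bits, nrow = 4L)
  vals <- as.integer(c(8, 4, 2, 1) %*% m)
  paste(c(0:9, letters[1:6])[vals + 1L], collapse = "")
}

#' Parse a hexadecimal fingerprint (most-significant-bit-first)
#' @param s Hexadecimal string.
#' @return Integer 0/1 vector of length `4 * nchar(s)`.
#' @export
fp_from_hex <- function(s) {
  digits <- strsplit(tolower(s), "", fixed = TRUE)[[1]]
  vals <- match(digits, c(0:9, letters[1:6])) - 1L
  if (anyNA(vals)) stop("invalid hexadecimal fingerprint: ", s)
  as.integer(rbind(vals %/% 8L, vals %/% 4L %% 2L, vals %/% 2L %% 2L, vals %% 2L))
}

# ---- internal validation helpers -------------------------------------------

as_fp_bits <- function(x) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || anyNA(x) || any(x != 0 & x != 1)) {
    stop("a fingerprint must be a binary (0/1) vector without NAs")
  }
  as.integer(x)
}

as_fp_matrix <- function(x) {
  if (!is.matrix(x)) stop("expected a fingerprint matrix (one row per compound)")
  storage.mode(x) <- "integer"
  if (anyNA(x) || any(x != 0L & x != 1L)) stop("fingerprint matrix must be binary 0/1")
  x
}
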