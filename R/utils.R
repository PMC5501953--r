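DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA strings
#'
#' Draws `n` independent DNA strings of length `len`, uniform over
#' A/C/G/T at every position. Uses the current RNG state.
#'
#' @param n number of strings
#' @param len string length
#' @return character vector of length `n`
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' One global seed fans out to per-stage seeds so that each stage is
#' independently reproducible. The derivation is a fixed affine map
#' modulo a prime below 2^31.
#'
#' @param seed integer global seed
#' @param k integer stage offset
#' @return integer sub-seed in [1, 2^31)
#' @export
sub_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), is.numeric(k))
  p <- 2147483629 # prime < 2^31
  as.integer((abs(as.numeric(seed)) %% p * 48271 + as.numeric(k) * 16807 + 1) %% p)
}

#' Pairwise Hamming distance between equal-length strings
#'
#' @param a,b character scalars of equal length
#' @return integer count of mismatching positions
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# encode DNA strings as an integer matrix (n x len), A=1..T=4
encode_dna <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), 0, 0))
  len <- nchar(x[1])
  m <- matrix(match(unlist(strsplit(x, "")), DNA_BASES), ncol = len, byrow = TRUE)
  storage.mode(m) <- "integer"
  m
}

# all-pairs Hamming distance matrix for equal-length strings (vectorized;
# one-hot crossproduct, fine for a few thousand strings)
hamming_matrix <- function(x) {
  enc <- encode_dna(x)
  n <- nrow(enc); len <- ncol(enc)
  X <- matrix(0, n, 4L * len)
  idx <- cbind(rep(seq_len(n), len), as.vector(enc) + 4L * rep(seq_len(len) - 1L, each = n))
  X[idx] <- 1
  len - tcrossprod(X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a list as pretty JSON (numbers unboxed)
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
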