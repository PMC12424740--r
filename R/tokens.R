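#' Amino-acid token vocabulary
#'
#' Sequences are modelled over a 21-symbol vocabulary: the 20 standard
#' amino acids (tokens 1--20, alphabetical by one-letter code) plus an
#' absorbing mask symbol (token 21) used by the discrete diffusion process.
#'
#' @format `aa_alphabet()` returns the 20 one-letter codes in token order;
#'   `mask_token()` returns the integer id of the mask symbol.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
mask_token <- function() 21L

#' @rdname aa_alphabet
#' @export
vocab_size <- function() 21L

#' Convert between token vectors and one-letter sequence strings
#'
#' @param tokens integer vector over 1..21 (21 renders as `"X"`).
#' @param x character string of one-letter amino-acid codes.
#' @return `tokens_to_string()` a string; `string_to_tokens()` an integer
#'   vector.
#' @export
tokens_to_string <- function(tokens) {
  stopifnot(all(tokens >= 1L, tokens <= 21L))
  letters21 <- c(aa_alphabet(), "X")
  paste(letters21[tokens], collapse = "")
}

#' @rdname tokens_to_string
#' @export
string_to_tokens <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  idx <- match(chars, c(aa_alphabet(), "X"))
  if (anyNA(idx)) {
    stop("unknown residue code(s): ", paste(unique(chars[is.na(idx)]), collapse = ", "))
  }
  idx
}

# deterministic half-away-from-zero rounding (base round() is banker's)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# set the session RNG from an optional seed, restoring nothing: callers that
# want full isolation use withr::with_seed in tests.
.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# rowwise log-softmax of a matrix
.log_softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  z <- x - m
  z - log(rowSums(exp(z)))
}

.softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# centroid-centering of an L x 3 coordinate matrix
center_coords <- function(x) {
  stopifnot(is.matrix(x), ncol(x) == 3L)
  sweep(x, 2L, colMeans(x))
}
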