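# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomized operations in the
# package route their seeds through this so that user RNG state is never
# clobbered.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Character matrix (position x sequence) for vectorized Hamming arithmetic.
# All inputs must have equal nchar.
char_matrix <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(character(), nrow = 0L, ncol = 0L))
  L <- nchar(x[[1L]])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = L, ncol = n)
}

#' Hamming distance between two equal-length sequences
#'
#' Counts positional mismatches (substitutions only; no indels).
#'
#' @param a,b character scalars of equal length.
#' @return Integer mismatch count.
#' @examples
#' hamming_distance("ACGT", "ACGA")
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance() requires equal-length sequences (",
         nchar(a), " vs ", nchar(b), ")")
  }
  sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
      strsplit(b, "", fixed = TRUE)[[1L]])
}

# One Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha # degenerate guard for tiny concentrations
  g / sum(g)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}
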