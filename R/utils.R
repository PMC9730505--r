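# Shared low-level helpers: amino-acid alphabet, deterministic hashing for
# per-allele model seeds, and fast string <-> index conversions.

#' The 20 standard amino acids (one-letter codes)
#'
#' Alphabet used for all sequence validation, synthetic registries and
#' position frequency matrices, in alphabetical order.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ASCII -> amino-acid index lookup (0 for non-amino-acid bytes)
.aa_lookup <- local({
  v <- integer(128)
  v[utf8ToInt(paste(AMINO_ACIDS, collapse = ""))] <- seq_along(AMINO_ACIDS)
  v
})

# Convert a character vector of equal-length peptides into an n x width
# integer matrix of amino-acid indices (1..20). Errors on invalid characters.
peptides_to_indices <- function(x, width) {
  if (length(x) == 0L) return(matrix(integer(0), 0L, width))
  if (any(nchar(x) != width)) {
    stop("all peptides must have length ", width, call. = FALSE)
  }
  codes <- utf8ToInt(paste(x, collapse = ""))
  idx <- .aa_lookup[codes]
  if (any(idx == 0L)) {
    bad <- intToUtf8(codes[idx == 0L][1L])
    stop("invalid amino-acid character '", bad, "'", call. = FALSE)
  }
  matrix(idx, nrow = length(x), ncol = width, byrow = TRUE)
}

# TRUE for strings made only of the 20 standard one-letter codes
is_valid_protein <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(FALSE)
    all(.aa_lookup[utf8ToInt(s)] > 0L)
  }, logical(1), USE.NAMES = FALSE)
}

# Deterministic 31-bit hash of a string combined with an integer seed.
# Used to give every HLA allele its own reproducible position-weight matrix.
# Plain polynomial rolling hash; doubles stay exact well below 2^53.
hash_string_seed <- function(text, seed) {
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(text)) h <- (h * 131 + code) %% m
  as.integer((h * 16777619 + (seed %% m)) %% m)
}

# Derive a stream of child seeds from one master seed (all < 2^31)
derive_seeds <- function(seed, n, salt = 0L) {
  m <- 2147483647
  vapply(seq_len(n), function(i) {
    as.integer(((seed %% m) * 48271 + i * 1103 + salt * 7919) %% m)
  }, integer(1))
}

# All contiguous windows of width w of one sequence, left to right
sliding_windows <- function(sequence, w) {
  L <- nchar(sequence)
  if (L < w) return(character(0))
  starts <- seq_len(L - w + 1L)
  substring(sequence, starts, starts + w - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
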