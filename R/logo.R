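# Positional amino-acid composition comparison between groups of 9-mer
# cores: position frequency matrices, per-position Jensen-Shannon
# divergence, and a label-permutation test with Benjamini-Hochberg
# adjustment across the nine positions.

#' Position frequency matrix of 9-mer cores
#'
#' Counts amino acids per position and converts to frequencies with a
#' Laplace pseudocount (frequencies at each position sum to 1).
#'
#' @param cores character vector of 9-mers.
#' @param pseudocount added to every cell before normalization
#'   (default 0.5).
#' @return A `pfm` list: `counts` and `frequencies` (9 x 20 matrices,
#'   rows = positions, columns = [AMINO_ACIDS]), `n_sequences`.
#' @export
position_frequencies <- function(cores, pseudocount = 0.5) {
  if (length(cores) == 0) stop("empty core set", call. = FALSE)
  idx <- peptides_to_indices(cores, 9L)
  counts <- matrix(0L, nrow = 9L, ncol = 20L,
                   dimnames = list(paste0("pos", 1:9), AMINO_ACIDS))
  for (p in 1:9) {
    counts[p, ] <- tabulate(idx[, p], nbins = 20L)
  }
  freq <- (counts + pseudocount) /
    (length(cores) + 20 * pseudocount)
  structure(list(counts = counts, frequencies = freq,
                 n_sequences = length(cores)),
            class = "pfm")
}

# Per-position JS divergence (bits) between two 9 x 20 frequency matrices
js_divergence <- function(f1, f2) {
  m <- (f1 + f2) / 2
  kl <- function(p, q) rowSums(ifelse(p > 0, p * log2(p / q), 0))
  (kl(f1, m) + kl(f2, m)) / 2
}

# Fast per-position counts from an index matrix over given rows
.pos_counts <- function(idx_off, rows, n_pos = 9L) {
  matrix(tabulate(idx_off[rows, ], nbins = n_pos * 20L),
         nrow = n_pos, byrow = TRUE)
}

#' Compare positional composition between two core groups
#'
#' Computes the per-position Jensen-Shannon divergence (bits) between the
#' pseudocounted position frequency matrices of two groups of 9-mers (e.g.
#' Lasso-selected vs unselected TcEMMs) and assesses it against a null
#' obtained by permuting group labels; p-values use the add-one estimator
#' `p = (1 + #perm >= observed) / (1 + n_perm)` and are BH-adjusted across
#' the nine positions.
#'
#' @param selected,unselected character vectors of 9-mers (each of size
#'   >= 2).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @param pseudocount Laplace pseudocount for the frequency matrices.
#' @return A `diff_result` data frame: `position`, `divergence`, `p`, `q`.
#' @export
compare_position_groups <- function(selected, unselected, n_perm = 1000L,
                                    seed = 1L, pseudocount = 0.5) {
  if (length(selected) < 2 || length(unselected) < 2) {
    stop("each group needs at least 2 cores", call. = FALSE)
  }
  n1 <- length(selected)
  all_cores <- c(selected, unselected)
  idx <- peptides_to_indices(all_cores, 9L)
  # offset positions so one tabulate() yields the whole 9 x 20 count table
  idx_off <- idx + matrix(rep((0:8) * 20L, each = nrow(idx)),
                          nrow = nrow(idx))
  total <- .pos_counts(idx_off, seq_len(nrow(idx)))
  to_freq <- function(cnt, n) (cnt + pseudocount) / (n + 20 * pseudocount)

  obs_c1 <- .pos_counts(idx_off, seq_len(n1))
  obs <- js_divergence(to_freq(obs_c1, n1),
                       to_freq(total - obs_c1, length(unselected)))
  exceed <- integer(9L)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      rows <- sample.int(nrow(idx), n1)
      c1 <- .pos_counts(idx_off, rows)
      d <- js_divergence(to_freq(c1, n1),
                         to_freq(total - c1, length(unselected)))
      exceed <- exceed + as.integer(d >= obs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  structure(data.frame(position = 1:9, divergence = obs, p = p,
                       q = bh_adjust(p)),
            class = c("diff_result", "data.frame"))
}
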