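## Internal helpers shared across modules.

#' @importFrom withr with_seed
run_seeded <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Empirical permutation p-value with the add-one rule
#'
#' p = (1 + #\{null >= observed\}) / (B + 1), which is never zero and is a
#' valid p-value for an exchangeable null.
#'
#' @param observed observed statistic (scalar).
#' @param null_values vector of statistics under the permutation null.
#' @return p-value in \[1/(B+1), 1\].
#' @export
empirical_pvalue <- function(observed, null_values) {
  stopifnot(length(observed) == 1L, is.finite(observed))
  (1 + sum(null_values >= observed)) / (length(null_values) + 1)
}

## Rank-statistic AUC with midranks for ties.
rank_auc <- function(score, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## All permutations of 1..n as an n! x n matrix (n <= 8; used for
## exhaustive permutation nulls at small sample sizes).
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L), drop = FALSE]
    out[row:(row + nrow(sub) - 1L), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rna_to_dna <- function(x) chartr("Uu", "Tt", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
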