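## Sequence-composition statistics for CCRs: dinucleotide-preserving
## shuffling (Altschul-Erickson Eulerian-walk construction) and k-mer /
## miRNA-complementarity enrichment against shuffled nulls.

#' Dinucleotide-preserving shuffle
#'
#' Returns a random sequence with exactly the same multiset of overlapping
#' dinucleotides as the input (and hence the same mononucleotide
#' composition, first and last residue). Uses the Eulerian-walk
#' construction: a random "last edge" is chosen for every vertex of the
#' dinucleotide multigraph such that the last edges form a tree into the
#' terminal residue, the remaining edge lists are permuted, and the walk is
#' read off.
#'
#' @param seq DNA string (A/C/G/T), length >= 2.
#' @param n number of shuffles to return.
#' @return shuffled DNA string (a character vector of length `n`).
#' @export
dinucleotide_shuffle <- function(seq, n = 1) {
  out <- dinuc_shuffle_cpp(toupper(seq), as.integer(n))
  if (n == 1) out[[1]] else out
}

ccr_sequences <- function(ccrs) {
  if (is.character(ccrs)) return(ccrs)
  if (is.data.frame(ccrs) && "sequence" %in% names(ccrs)) return(ccrs$sequence)
  stop("ccrs must be a character vector or a CCR data.frame")
}

ccr_center_offsets <- function(ccrs, flank = 20) {
  if (is.data.frame(ccrs) && "center_offset" %in% names(ccrs))
    return(ccrs$center_offset)
  rep(flank, length(ccr_sequences(ccrs)))
}

#' k-mer enrichment in CCRs against dinucleotide-preserving shuffles
#'
#' Counts every one of the 4^k possible k-mers over all CCR sequences
#' (overlapping occurrences) and compares each count to its null
#' distribution over `n_shuffles` dinucleotide-preserving shuffles of the
#' CCR set. Reports a z-score (`(obs - mean) / sd`, zero when the null sd is
#' zero), an add-one empirical p-value and Benjamini-Hochberg q-values
#' across all 4^k k-mers. Rows are ordered by (q, -z, p) so the most
#' enriched k-mer comes first.
#'
#' @param ccrs CCR data.frame from [extract_ccrs()] or character vector.
#' @param k k-mer length, 4..10.
#' @param n_shuffles number of shuffled CCR sets (>= 100).
#' @param seed RNG seed.
#' @param positional if `TRUE`, attach a `positional_profile` attribute:
#'   a k-mers x offsets count matrix of k-mer start positions relative to
#'   the CCR center.
#' @return data.frame with columns `kmer`, `observed_count`, `shuffle_mean`,
#'   `shuffle_sd`, `z_score`, `p_value`, `bh_q`.
#' @export
kmer_enrichment <- function(ccrs, k = 7, n_shuffles = 100, seed = NULL,
                            positional = FALSE) {
  seqs <- ccr_sequences(ccrs)
  if (length(seqs) == 0) stop("empty CCR list")
  if (k < 4 || k > 10) stop("k must be in [4, 10]")
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  count_set <- function(ss) {
    colSums(Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(ss),
                                                 width = k))
  }
  obs <- count_set(seqs)
  null_counts <- run_seeded(seed, {
    shuf <- lapply(seqs, dinuc_shuffle_cpp, B = n_shuffles)
    m <- matrix(0, n_shuffles, length(obs))
    for (b in seq_len(n_shuffles)) {
      m[b, ] <- count_set(vapply(shuf, `[`, "", b))
    }
    m
  })
  mu <- colMeans(null_counts)
  sdv <- apply(null_counts, 2, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  exceed <- colSums(null_counts >= rep(obs, each = n_shuffles))
  p <- (1 + exceed) / (n_shuffles + 1)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(kmer = names(obs), observed_count = as.integer(obs),
                    shuffle_mean = mu, shuffle_sd = sdv, z_score = z,
                    p_value = p, bh_q = q, stringsAsFactors = FALSE)
  if (positional) {
    centers <- ccr_center_offsets(ccrs)
    lens <- nchar(seqs)
    offs <- unlist(lapply(seq_along(seqs), function(i) {
      if (lens[i] < k) return(integer(0))
      seq.int(0L, lens[i] - k) - centers[i]
    }))
    kms <- unlist(lapply(seq_along(seqs), function(i) {
      if (lens[i] < k) return(character(0))
      st <- seq.int(1L, lens[i] - k + 1L)
      substring(seqs[i], st, st + k - 1L)
    }))
    rng <- range(offs)
    prof <- matrix(0L, length(obs), rng[2] - rng[1] + 1L,
                   dimnames = list(names(obs), as.character(rng[1]:rng[2])))
    tab <- table(factor(kms, levels = names(obs)), factor(offs, levels = rng[1]:rng[2]))
    prof[] <- as.integer(tab)
    attr(out, "positional_profile") <- prof
  }
  ord <- order(out$bh_q, -out$z_score, out$p_value, out$kmer)
  out <- out[ord, ]
  rownames(out) <- NULL
  if (positional) attr(out, "positional_profile") <-
    attr(out, "positional_profile") %||% NULL
  out
}

#' Enrichment of miRNA-complementary k-mers in CCRs
#'
#' For each miRNA, each k in `k_range` and each start position within
#' miRNA positions 1..10, counts the CCRs containing the reverse complement
#' of that miRNA subsequence, and computes enrichment statistics against
#' `n_shuffles` dinucleotide-preserving shuffles of the CCR set (add-one
#' empirical p, z-score, BH q across all records).
#'
#' @param ccrs CCR data.frame or character vector of CCR sequences.
#' @param mirna_sequences named character vector of mature miRNA sequences
#'   (RNA or DNA), each >= 10 nt.
#' @param k_range word lengths to test (subsequences of positions 1..10).
#' @param n_shuffles shuffled CCR sets (>= 100).
#' @param seed RNG seed.
#' @return data.frame with `mirna_id`, `k`, `start` (1-based miRNA
#'   position), `site_sequence`, `observed_count`, `shuffle_mean`,
#'   `shuffle_sd`, `z_score`, `p_value`, `bh_q`.
#' @export
complementarity_enrichment <- function(ccrs, mirna_sequences, k_range = 6:10,
                                       n_shuffles = 100, seed = NULL) {
  seqs <- ccr_sequences(ccrs)
  if (length(seqs) == 0) stop("empty CCR list")
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  probes <- do.call(rbind, lapply(names(mirna_sequences), function(id) {
    mir <- rna_to_dna(toupper(mirna_sequences[[id]]))
    rows <- list()
    for (k in k_range) {
      if (k > 10 || k > nchar(mir)) {
        warning("skipping k=", k, " for ", id, ": exceeds available positions")
        next
      }
      for (start in seq_len(11 - k)) {
        sub <- substr(mir, start, start + k - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = id, k = k, start = start,
          site_sequence = revcomp_dna(sub), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }))
  count_in <- function(ss) {
    vapply(probes$site_sequence,
           function(p) sum(grepl(p, ss, fixed = TRUE)), 0)
  }
  obs <- count_in(seqs)
  null_counts <- run_seeded(seed, {
    shuf <- lapply(seqs, dinuc_shuffle_cpp, B = n_shuffles)
    m <- matrix(0, n_shuffles, nrow(probes))
    for (b in seq_len(n_shuffles)) {
      m[b, ] <- count_in(vapply(shuf, `[`, "", b))
    }
    m
  })
  mu <- colMeans(null_counts)
  sdv <- apply(null_counts, 2, stats::sd)
  probes$observed_count <- as.integer(obs)
  probes$shuffle_mean <- mu
  probes$shuffle_sd <- sdv
  probes$z_score <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  probes$p_value <- (1 + colSums(null_counts >= rep(obs, each = n_shuffles))) /
    (n_shuffles + 1)
  probes$bh_q <- stats::p.adjust(probes$p_value, method = "BH")
  rownames(probes) <- NULL
  probes
}
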