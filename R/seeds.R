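## Canonical miRNA seed-site calling within CCRs. Site types follow the
## standard nomenclature: the seed is miRNA positions 2-8; a target site is
## the reverse complement of the seed (7mer-m8), the reverse complement of
## positions 2-7 followed by an A (7mer-1A), both combined (8mer: reverse
## complement of 2-8 plus A opposite position 1), or a perfect match to
## positions 1-7 (6mer-1-7, requiring the mature sequence).

#' Target-side site sequences for a miRNA family
#'
#' @param seed_2_8 7-nt RNA seed (miRNA positions 2-8).
#' @param mature optional mature RNA sequence (for the 1-7 site).
#' @return named character vector of DNA site sequences (`8mer`, `7mer-m8`,
#'   `7mer-1A`, and `6mer-1-7` when a mature sequence is given).
#' @export
seed_site_sequences <- function(seed_2_8, mature = NULL) {
  seed <- rna_to_dna(toupper(seed_2_8))
  if (nchar(seed) != 7 || !grepl("^[ACGT]+$", seed))
    stop("seed must be a 7-nt RNA/DNA string")
  m8  <- revcomp_dna(seed)                       # complement of positions 2-8
  s <- c(`8mer` = paste0(m8, "A"),
         `7mer-m8` = m8,
         `7mer-1A` = paste0(revcomp_dna(substr(seed, 1, 6)), "A"))
  if (!is.null(mature) && length(mature) && nzchar(mature[1])) {
    mat <- rna_to_dna(toupper(mature[1]))
    if (nchar(mat) >= 7)
      s <- c(s, `6mer-1-7` = revcomp_dna(substr(mat, 1, 7)))
  }
  s
}

match_starts <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Call canonical seed sites in CCRs
#'
#' Scans every CCR sequence for target sites of every miRNA family. Each
#' occurrence is reported once with its most specific type: a 7mer-m8 match
#' that is the prefix of an 8mer is reported as 8mer only, a 7mer-1A match
#' contained in an 8mer is suppressed, and a 1-7 match that restates an
#' already-called seed match at the same location is suppressed. RNA seeds
#' are matched against DNA CCRs via U -> T.
#'
#' @param ccrs CCR data.frame (needs `ccr_id`, `sequence`) or a named
#'   character vector of CCR sequences.
#' @param families miRNA family data.frame as from [read_mirna_families()]
#'   (`family_id`, `seed_2_8`, optional list-column `mature_sequences`).
#' @return data.frame with `ccr_id`, `family_id`, `site_type`,
#'   `site_start_offset` (0-based within the CCR).
#' @export
call_seed_sites <- function(ccrs, families) {
  if (is.character(ccrs)) {
    ids <- names(ccrs) %||% paste0("ccr_", seq_along(ccrs))
    ccrs <- data.frame(ccr_id = ids, sequence = unname(ccrs),
                       stringsAsFactors = FALSE)
  }
  fam_sites <- lapply(seq_len(nrow(families)), function(i) {
    mat <- families$mature_sequences[[i]] %||% NULL
    seed_site_sequences(families$seed_2_8[i],
                        if (length(mat)) mat[1] else NULL)
  })
  out <- vector("list", nrow(ccrs) * nrow(families))
  n <- 0L
  for (ci in seq_len(nrow(ccrs))) {
    seq <- toupper(ccrs$sequence[ci])
    for (fi in seq_len(nrow(families))) {
      sites <- fam_sites[[fi]]
      o8  <- match_starts(sites[["8mer"]], seq)
      o7m <- match_starts(sites[["7mer-m8"]], seq)
      o7a <- match_starts(sites[["7mer-1A"]], seq)
      o7m_rep <- setdiff(o7m, o8)             # 8mer begins at the same offset
      o7a_rep <- setdiff(o7a, o8 + 1L)        # 8mer suffix is the 7mer-1A
      calls <- data.frame(site_type = character(0), off = integer(0))
      if (length(o8))
        calls <- rbind(calls, data.frame(site_type = "8mer", off = o8))
      if (length(o7m_rep))
        calls <- rbind(calls, data.frame(site_type = "7mer-m8", off = o7m_rep))
      if (length(o7a_rep))
        calls <- rbind(calls, data.frame(site_type = "7mer-1A", off = o7a_rep))
      if ("6mer-1-7" %in% names(sites)) {
        o6 <- match_starts(sites[["6mer-1-7"]], seq)
        # the 1-7 match restates a 2-8 match shifted by one, or a 1A match
        # at the same offset; report only novel occurrences
        o6_rep <- setdiff(o6, c(o8, o8 + 1L, o7m, o7m + 1L, o7a))
        if (length(o6_rep))
          calls <- rbind(calls, data.frame(site_type = "6mer-1-7", off = o6_rep))
      }
      if (nrow(calls)) {
        n <- n + 1L
        out[[n]] <- data.frame(ccr_id = ccrs$ccr_id[ci],
                               family_id = families$family_id[fi],
                               site_type = calls$site_type,
                               site_start_offset = calls$off - 1L,
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0L)
    return(data.frame(ccr_id = character(0), family_id = character(0),
                      site_type = character(0), site_start_offset = integer(0)))
  res <- do.call(rbind, out[seq_len(n)])
  res <- res[order(res$ccr_id, res$family_id, res$site_start_offset), ]
  rownames(res) <- NULL
  res
}

#' Aggregate seed-site calls to (family, gene) interactions
#'
#' @param sites data.frame from [call_seed_sites()].
#' @param ccrs CCR data.frame carrying `ccr_id` and `transcript_id`.
#' @param transcript_to_gene optional named vector mapping transcript ids to
#'   gene ids (identity if omitted).
#' @return data.frame with `family_id`, `gene_id`, `n_sites`.
#' @export
sites_to_interactions <- function(sites, ccrs, transcript_to_gene = NULL) {
  gene <- ccrs$transcript_id[match(sites$ccr_id, ccrs$ccr_id)]
  if (!is.null(transcript_to_gene)) gene <- unname(transcript_to_gene[gene])
  agg <- stats::aggregate(list(n_sites = sites$site_type),
                          by = list(family_id = sites$family_id, gene_id = gene),
                          FUN = length)
  agg[order(agg$family_id, agg$gene_id), ]
}
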