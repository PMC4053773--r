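## AGO2 PAR-CLIP binding-site identification: read clustering, crosslink-
## centered regions (CCRs) and transcript-region annotation. All work is
## done in transcript space with 0-based half-open coordinates; T-to-C
## conversions are assessed on the transcribed strand.

#' Cluster overlapping PAR-CLIP reads
#'
#' Reads longer than 20 nt that transitively overlap (single-linkage, at
#' least 1 bp) on the same transcript form clusters. Clusters with fewer
#' than `min_reads` reads or with fewer than `min_xlink_frac` crosslinked
#' (T-to-C carrying) reads are discarded.
#'
#' @param reads data.frame as from [read_aligned_reads()].
#' @param min_reads minimum reads per retained cluster.
#' @param min_xlink_frac minimum fraction of crosslinked reads.
#' @param min_read_len minimum read length (reads shorter than this are
#'   ignored; the default keeps reads > 20 nt).
#' @return list of clusters; each is a list with `cluster_id`,
#'   `transcript_id`, `start`, `end`, `n_reads`, `crosslinked_fraction`,
#'   `conversion_profile` (named integer vector, position -> count) and
#'   `major_t2c_position` (5'-most maximum, `NA` if no conversions).
#' @export
cluster_reads <- function(reads, min_reads = 5, min_xlink_frac = 0.2,
                          min_read_len = 21) {
  if (nrow(reads) == 0) return(list())
  reads <- reads[reads$end - reads$start >= min_read_len, , drop = FALSE]
  if (nrow(reads) == 0) return(list())
  reads <- reads[order(reads$transcript_id, reads$start, reads$end), , drop = FALSE]
  clusters <- list()
  idx <- integer(0); cur_end <- -Inf; cur_tx <- ""
  flush <- function(idx) {
    if (!length(idx)) return(NULL)
    sub <- reads[idx, , drop = FALSE]
    n <- nrow(sub)
    xl <- vapply(sub$t2c_positions, function(p) length(p) > 0, TRUE)
    frac <- mean(xl)
    if (n < min_reads || frac < min_xlink_frac) return(NULL)
    prof <- table(unlist(sub$t2c_positions))
    prof <- stats::setNames(as.integer(prof), names(prof))
    pos <- as.integer(names(prof))
    major <- if (length(prof)) min(pos[prof == max(prof)]) else NA_integer_
    list(transcript_id = sub$transcript_id[1],
         start = min(sub$start), end = max(sub$end),
         n_reads = n, crosslinked_fraction = frac,
         conversion_profile = prof, major_t2c_position = major)
  }
  for (i in seq_len(nrow(reads))) {
    if (reads$transcript_id[i] != cur_tx || reads$start[i] >= cur_end) {
      cl <- flush(idx)
      if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
      idx <- i; cur_end <- reads$end[i]; cur_tx <- reads$transcript_id[i]
    } else {
      idx <- c(idx, i)
      cur_end <- max(cur_end, reads$end[i])
    }
  }
  cl <- flush(idx)
  if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
  for (k in seq_along(clusters)) clusters[[k]]$cluster_id <- sprintf("cluster_%04d", k)
  clusters
}

#' Fraction of crosslinked reads
#'
#' The T-to-C conversion rate of a read set: the fraction of reads carrying
#' at least one T-to-C conversion.
#'
#' @param reads data.frame of aligned reads.
#' @return scalar in \[0, 1\].
#' @export
conversion_rate <- function(reads) {
  if (nrow(reads) == 0) stop("conversion_rate on empty read set")
  mean(vapply(reads$t2c_positions, function(p) length(p) > 0, TRUE))
}

#' Extract the crosslink-centered region (CCR) of a cluster
#'
#' The CCR is the 41-nt window comprising `flank` (default 20) nucleotides
#' upstream and downstream of the cluster's major T-to-C conversion site
#' (ties broken toward the 5' end). Windows running off a transcript end are
#' clipped, never padded, and flagged as truncated.
#'
#' @param cluster one element of [cluster_reads()] output.
#' @param transcript_seq the transcript's DNA sequence (character).
#' @param flank nucleotides on each side of the crosslink.
#' @return list with `ccr_id`, `cluster_id`, `transcript_id`, `sequence`,
#'   `center_position` (transcript coordinate), `start` (transcript
#'   coordinate of the first CCR base), `center_offset` (0-based offset of
#'   the crosslink within the CCR) and `truncated_flag`.
#' @export
extract_ccr <- function(cluster, transcript_seq, flank = 20) {
  center <- cluster$major_t2c_position
  L <- nchar(transcript_seq)
  if (is.na(center) || center < 0 || center >= L)
    stop("major conversion position outside transcript")
  s <- max(0L, center - flank)
  e <- min(L, center + flank + 1L)
  list(ccr_id = paste0("ccr_", cluster$cluster_id),
       cluster_id = cluster$cluster_id,
       transcript_id = cluster$transcript_id,
       sequence = substr(transcript_seq, s + 1L, e),
       center_position = center,
       start = s,
       center_offset = center - s,
       truncated_flag = (e - s) < (2L * flank + 1L))
}

## Convenience: CCRs for all clusters, given a named transcript sequence set.
#' @rdname extract_ccr
#' @param clusters list of clusters.
#' @param transcripts named character vector of transcript sequences.
#' @export
extract_ccrs <- function(clusters, transcripts, flank = 20) {
  out <- lapply(clusters, function(cl) {
    seq <- transcripts[[cl$transcript_id]]
    if (is.null(seq)) stop("transcript absent from sequence set: ", cl$transcript_id)
    extract_ccr(cl, seq, flank)
  })
  data.frame(ccr_id = vapply(out, `[[`, "", "ccr_id"),
             cluster_id = vapply(out, `[[`, "", "cluster_id"),
             transcript_id = vapply(out, `[[`, "", "transcript_id"),
             sequence = vapply(out, `[[`, "", "sequence"),
             center_position = as.integer(vapply(out, `[[`, 0, "center_position")),
             start = as.integer(vapply(out, `[[`, 0, "start")),
             center_offset = as.integer(vapply(out, `[[`, 0, "center_offset")),
             truncated_flag = vapply(out, `[[`, TRUE, "truncated_flag"),
             stringsAsFactors = FALSE)
}

#' Annotate clusters by transcript region
#'
#' Labels each cluster with the region (5'UTR / CDS / 3'UTR) holding the
#' majority of its span; ties go to the 3'-most region. Clusters on
#' transcripts absent from the model are labeled `unannotated`. Fractions
#' are reported over annotated clusters and sum to 1.
#'
#' @param clusters list of clusters from [cluster_reads()].
#' @param model region model data.frame from [read_transcript_model()].
#' @return list with `labels` (character vector, one per cluster) and
#'   `fractions` (named numeric over `5UTR`, `CDS`, `3UTR`).
#' @export
annotate_regions <- function(clusters, model) {
  labels <- vapply(clusters, function(cl) {
    rows <- model[model$transcript_id == cl$transcript_id, , drop = FALSE]
    if (nrow(rows) == 0) return("unannotated")
    ov <- pmin(rows$end, cl$end) - pmax(rows$start, cl$start)
    ov[ov < 0] <- 0
    if (all(ov == 0)) return("unannotated")
    best <- which(ov == max(ov))
    if (length(best) > 1) best <- best[which.max(rows$start[best])]  # 3'-most
    rows$region[best]
  }, "")
  annotated <- labels[labels != "unannotated"]
  fr <- if (length(annotated))
    table(factor(annotated, levels = c("5UTR", "CDS", "3UTR"))) / length(annotated)
  else table(factor(character(0), levels = c("5UTR", "CDS", "3UTR")))
  list(labels = labels, fractions = stats::setNames(as.numeric(fr), names(fr)))
}

#' Select the top-expressed miRNAs covering a read-frequency quantile
#'
#' Returns the smallest set of miRNAs, in descending relative read
#' frequency, whose cumulative RRF reaches `coverage` (e.g. the
#' top-expressed miRNAs accounting for 95\% of miRNA reads). miRNAs tied
#' with the last included value are all included.
#'
#' @param rrf named numeric vector of RRF values summing to 1.
#' @param coverage target cumulative RRF, in (0, 1].
#' @return character vector of miRNA ids.
#' @export
select_top_mirnas <- function(rrf, coverage = 0.95) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  if (abs(sum(rrf) - 1) > 1e-6) stop("RRF values must sum to 1")
  ord <- order(-rrf, names(rrf))
  sorted <- rrf[ord]
  k <- which(cumsum(sorted) >= coverage - 1e-12)[1]
  cut_val <- sorted[k]
  names(sorted)[seq_along(sorted) <= k | sorted == cut_val]
}
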