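## Readers and writers for the plain-text formats the pipeline consumes and
## emits. Matrices and annotation tables travel as TSV with a header row;
## sequences as FASTA (Biostrings); gene sets as GMT; transcript models as
## BED (0-based half-open) or GFF3 (1-based inclusive, converted on ingest);
## aligned reads as SAM or a 6-column TSV. Internal coordinates are always
## 0-based half-open.

#' Write / read an ExpressionMatrix as TSV
#'
#' The first column holds entity ids; a leading `#` comment line records the
#' entity kind and scale so that `read_expression_matrix()` round-trips the
#' object exactly.
#'
#' @param x an `ExpressionMatrix`.
#' @param path file path.
#' @return `read_expression_matrix` returns an `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#mirti entity_kind=%s scale=%s", em_kind(x), em_scale(x)), con)
  df <- data.frame(entity_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub(".*entity_kind=(\\S+).*", "\\1", first)
  scl  <- sub(".*scale=(\\S+).*", "\\1", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, entity_kind = kind, scale = scl)
}

#' Read / write GMT gene sets
#'
#' One set per line: set id, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions, recycled.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read / write transcript sequences (FASTA)
#' @param path FASTA file.
#' @param seqs named character vector or `DNAStringSet`.
#' @return `read_fasta` returns a named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a transcript region model from BED or GFF3
#'
#' The model assigns `5UTR` / `CDS` / `3UTR` intervals to transcripts, in
#' transcript coordinates. BED input is taken as 0-based half-open and GFF3
#' as 1-based inclusive; both are converted to the internal 0-based
#' half-open convention. The feature/name field must be one of `5UTR`,
#' `CDS`, `3UTR` (GFF3 types `five_prime_UTR`/`three_prime_UTR` are mapped).
#'
#' @param path BED (`.bed`) or GFF3 (`.gff`, `.gff3`) file.
#' @return data.frame with columns `transcript_id`, `region`, `start`, `end`.
#' @export
read_transcript_model <- function(path) {
  gr <- rtracklayer::import(path)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  label <- if (is_gff) as.character(gr$type) else as.character(gr$name)
  label <- c(five_prime_UTR = "5UTR", three_prime_UTR = "3UTR",
             CDS = "CDS", `5UTR` = "5UTR", `3UTR` = "3UTR")[label]
  if (anyNA(label)) stop("unrecognized region label in ", path)
  data.frame(transcript_id = as.character(GenomicRanges::seqnames(gr)),
             region = label,
             start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param df data.frame with `transcript_id`, `start`, `end` (0-based
#'   half-open) and optionally `name` and `score`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$transcript_id, start = df$start, end = df$end,
                    name = df$name %||% ".", score = df$score %||% 0,
                    strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a miRNA family table
#'
#' TSV columns: `family_id`, `member_ids` (comma-separated), `seed_2_8`
#' (7-nt RNA seed, miRNA positions 2-8) and optional `mature_sequences`
#' (comma-separated RNA, parallel to members). Families are named after
#' their lowest-numbered member.
#'
#' @param path TSV file.
#' @param families data.frame as returned by `read_mirna_families`.
#' @return data.frame with list-columns `member_ids`, `mature_sequences`.
#' @export
read_mirna_families <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("family_id", "member_ids", "seed_2_8")
  if (!all(need %in% names(df))) stop("family table must have columns ",
                                      paste(need, collapse = ", "))
  if (!all(nchar(df$seed_2_8) == 7L & grepl("^[ACGU]+$", df$seed_2_8)))
    stop("seeds must be 7-nt RNA strings")
  df$member_ids <- strsplit(df$member_ids, ",", fixed = TRUE)
  df$mature_sequences <- if ("mature_sequences" %in% names(df))
    strsplit(df$mature_sequences, ",", fixed = TRUE) else
    replicate(nrow(df), character(0), simplify = FALSE)
  df
}

#' @rdname read_mirna_families
#' @export
write_mirna_families <- function(families, path) {
  out <- data.frame(
    family_id = families$family_id,
    member_ids = vapply(families$member_ids, paste, "", collapse = ","),
    seed_2_8 = families$seed_2_8,
    mature_sequences = vapply(families$mature_sequences, paste, "", collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a TargetScan-summary-style prediction table
#'
#' TSV with one row per (miRNA family, gene) pair carrying the aggregate
#' conservation (PCT) score, total context score, per-site-type counts for
#' conserved and non-conserved 7mer-m8 / 7mer-1A / 8mer sites, their totals
#' and a conserved flag.
#'
#' @param path TSV file.
#' @param predictions data.frame of predictions.
#' @return data.frame.
#' @export
read_target_predictions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- prediction_columns()
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("prediction table missing columns: ",
                         paste(miss, collapse = ", "))
  cnt <- grep("^n_", need, value = TRUE)
  if (any(df[cnt] < 0)) stop("site counts must be non-negative")
  if (any(df$n_conserved_sites !=
          df$n_cons_7m8 + df$n_cons_7a1 + df$n_cons_8mer) ||
      any(df$n_nonconserved_sites !=
          df$n_noncons_7m8 + df$n_noncons_7a1 + df$n_noncons_8mer))
    stop("site totals do not match per-type counts")
  df
}

prediction_columns <- function() {
  c("family_id", "gene_id", "aggregate_pct", "total_context_score",
    "n_cons_7m8", "n_cons_7a1", "n_cons_8mer",
    "n_noncons_7m8", "n_noncons_7a1", "n_noncons_8mer",
    "n_conserved_sites", "n_nonconserved_sites", "conserved_flag")
}

#' @rdname read_target_predictions
#' @export
write_target_predictions <- function(predictions, path) {
  utils::write.table(predictions[prediction_columns()], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotation
#'
#' TSV with `sample_id`, `subtype` and optional phenotype columns:
#' `lymph_node_positive`, `lymphovascular_invasion` (0/1),
#' `tumor_size_class` (`<2`, `2-5`, `>5`), `grade` (`good`, `moderate`,
#' `poor`), `time_to_metastasis`/`metastasis_event`,
#' `overall_survival`/`survival_event`. Missing phenotype values are
#' permitted and dropped per-analysis.
#'
#' @param path TSV file.
#' @param annotation data.frame.
#' @return data.frame.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  if (!all(c("sample_id", "subtype") %in% names(df)))
    stop("sample annotation needs sample_id and subtype columns")
  subtypes <- c("basal-like", "HER2", "luminal A", "luminal B",
                "normal-like", "unassigned")
  if (!all(df$subtype %in% subtypes))
    stop("unknown subtype value(s): ",
         paste(setdiff(df$subtype, subtypes), collapse = ", "))
  for (col in c("tumor_size_class", "grade")) {
    if (col %in% names(df)) {
      lv <- if (col == "grade") c("good", "moderate", "poor") else c("<2", "2-5", ">5")
      bad <- !is.na(df[[col]]) & !(df[[col]] %in% lv)
      if (any(bad)) stop("invalid ", col, " value(s)")
    }
  }
  for (col in c("time_to_metastasis", "overall_survival")) {
    if (col %in% names(df) && any(df[[col]] < 0, na.rm = TRUE))
      stop(col, " must be non-negative")
  }
  df
}

#' @rdname read_sample_annotation
#' @export
write_sample_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write PAR-CLIP aligned reads (tabular)
#'
#' The tabular interchange format has columns `read_id`, `transcript_id`,
#' `start`, `end` (0-based half-open, transcript coordinates), `sequence`
#' and `t2c_positions` (semicolon-separated transcript coordinates of
#' observed T-to-C conversions; empty for non-crosslinked reads).
#'
#' @param path TSV file.
#' @param reads data.frame of aligned reads (list-column `t2c_positions`).
#' @return data.frame with a list-column `t2c_positions` (integer vectors).
#' @export
read_aligned_reads <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(t2c_positions = "character"))
  need <- c("read_id", "transcript_id", "start", "end", "sequence", "t2c_positions")
  if (!all(need %in% names(df)))
    stop("read table must have columns ", paste(need, collapse = ", "))
  df$t2c_positions <- lapply(strsplit(df$t2c_positions, ";", fixed = TRUE),
                             function(p) as.integer(p[nzchar(p)]))
  validate_reads(df)
}

#' @rdname read_aligned_reads
#' @export
write_aligned_reads <- function(reads, path) {
  out <- reads
  out$t2c_positions <- vapply(reads$t2c_positions, paste, "", collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_reads <- function(df) {
  bad <- which(df$end - df$start != nchar(df$sequence))
  if (length(bad)) stop("read span does not match sequence length at row ", bad[1])
  ok <- mapply(function(p, s, e) all(p >= s & p < e),
               df$t2c_positions, df$start, df$end)
  if (!all(ok)) stop("T-to-C position outside read span at row ", which(!ok)[1])
  df
}

#' Read PAR-CLIP aligned reads from SAM
#'
#' Parses a SAM file and derives T-to-C conversion positions from the MD tag
#' (mismatches where the reference base is T and the read base is C, on the
#' transcribed strand). Only simple ungapped alignments (CIGAR `<n>M`) are
#' supported, which covers transcript-space PAR-CLIP alignments.
#'
#' @param path SAM file with `@SQ` headers and MD tags.
#' @return data.frame in the same shape as [read_aligned_reads()].
#' @export
read_aligned_reads_sam <- function(path) {
  lines <- readLines(path)
  rec <- lines[!startsWith(lines, "@")]
  rec <- rec[nzchar(rec)]
  fields <- strsplit(rec, "\t", fixed = TRUE)
  parse1 <- function(f) {
    if (length(f) < 11) stop("malformed SAM record: ", f[1])
    cigar <- f[6]
    if (!grepl("^[0-9]+M$", cigar))
      stop("only ungapped <n>M alignments supported (read ", f[1], ")")
    pos0 <- as.integer(f[4]) - 1L  # SAM is 1-based
    seq <- f[10]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", f[-(1:11)], value = TRUE)[1])
    t2c <- integer(0)
    if (!is.na(md)) {
      toks <- regmatches(md, gregexpr("[0-9]+|\\^[ACGTN]+|[ACGTN]", md))[[1]]
      off <- 0L
      for (tk in toks) {
        if (grepl("^[0-9]+$", tk)) {
          off <- off + as.integer(tk)
        } else if (startsWith(tk, "^")) {
          stop("deletions unsupported in read ", f[1])
        } else {  # single mismatched reference base
          if (tk == "T" && substr(seq, off + 1L, off + 1L) == "C")
            t2c <- c(t2c, pos0 + off)
          off <- off + 1L
        }
      }
    }
    list(read_id = f[1], transcript_id = f[3], start = pos0,
         end = pos0 + nchar(seq), sequence = seq, t2c = list(t2c))
  }
  parsed <- lapply(fields, parse1)
  df <- data.frame(read_id = vapply(parsed, `[[`, "", "read_id"),
                   transcript_id = vapply(parsed, `[[`, "", "transcript_id"),
                   start = vapply(parsed, `[[`, 0L, "start"),
                   end = vapply(parsed, `[[`, 0L, "end"),
                   sequence = vapply(parsed, `[[`, "", "sequence"),
                   stringsAsFactors = FALSE)
  df$t2c_positions <- lapply(parsed, function(p) p$t2c[[1]])
  validate_reads(df)
}

#' Read / write a (family, gene) interaction map
#'
#' TSV with columns `family_id`, `gene_id` and optionally `source`
#' (`targetscan_conserved`, `targetscan_nonconserved`, `parclip`, `model`).
#'
#' @param path TSV file.
#' @param map data.frame.
#' @return data.frame.
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("family_id", "gene_id") %in% names(df)))
    stop("target map needs family_id and gene_id columns")
  df
}

#' @rdname read_target_map
#' @export
write_target_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
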