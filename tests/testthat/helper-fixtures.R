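# Shared fixtures and independent oracles, built in code at test time.

make_em <- function(values, kind = "mirna", scale = "counts",
                    entities = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- entities %||% rownames(values) %||%
    paste0("e", seq_len(nrow(values)))
  colnames(values) <- samples %||% colnames(values) %||%
    paste0("s", seq_len(ncol(values)))
  expression_matrix(values, entity_kind = kind, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Random miRNA family table with mature sequences (positions 2-8 = seed).
random_family_table <- function(n) {
  seeds <- character(0)
  while (length(seeds) < n) {
    s <- random_rna_str(7)
    if (!s %in% seeds) seeds <- c(seeds, s)
  }
  fam <- data.frame(family_id = sprintf("fam%02d", seq_len(n)),
                    seed_2_8 = seeds, stringsAsFactors = FALSE)
  fam$member_ids <- as.list(fam$family_id)
  fam$mature_sequences <- lapply(seeds, function(s)
    paste0(substr(random_rna_str(1), 1, 1), s, random_rna_str(13)))
  fam
}

# Dinucleotide count vector of a sequence (independent of the package code).
dinuc_counts <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  sort(table(paste0(v[-length(v)], v[-1])))
}

# Brute-force seed-site oracle. Builds site patterns by explicit
# base-by-base complementation and scans every offset with substring
# equality, then applies the package's stated most-specific-type rules.
oracle_seed_sites <- function(ccr_seq, seed_rna, mature_rna = NULL) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_chars <- function(x) {
    paste(rev(unname(comp[strsplit(chartr("U", "T", toupper(x)), "")[[1]]])),
          collapse = "")
  }
  scan <- function(pat) {
    k <- nchar(pat)
    L <- nchar(ccr_seq)
    if (L < k) return(integer(0))
    i <- seq_len(L - k + 1)
    i[substring(ccr_seq, i, i + k - 1) == pat]
  }
  seed <- chartr("U", "T", toupper(seed_rna))
  o8 <- scan(paste0(rc_chars(seed), "A"))
  o7m <- scan(rc_chars(seed))
  o7a <- scan(paste0(rc_chars(substr(seed, 1, 6)), "A"))
  rows <- list()
  add <- function(type, off) {
    if (length(off))
      rows[[length(rows) + 1L]] <<- data.frame(site_type = type,
                                               site_start_offset = off - 1L)
  }
  add("8mer", o8)
  add("7mer-m8", setdiff(o7m, o8))
  add("7mer-1A", setdiff(o7a, o8 + 1L))
  if (!is.null(mature_rna) && length(mature_rna) && nzchar(mature_rna[1])) {
    o6 <- scan(rc_chars(substr(chartr("U", "T", toupper(mature_rna[1])), 1, 7)))
    add("6mer-1-7", setdiff(o6, c(o8, o8 + 1L, o7m, o7m + 1L, o7a)))
  }
  if (!length(rows))
    return(data.frame(site_type = character(0), site_start_offset = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$site_start_offset, out$site_type), , drop = FALSE]
}

pair_key <- function(f, g) paste(f, g, sep = "\r")

# Aligned-read fixture builder.
make_reads <- function(tx, starts, len = 25, t2c = NULL, prefix = "r") {
  n <- length(starts)
  df <- data.frame(read_id = paste0(prefix, seq_len(n)),
                   transcript_id = tx, start = starts, end = starts + len,
                   sequence = vapply(seq_len(n), function(i) random_dna_str(len), ""),
                   stringsAsFactors = FALSE)
  df$t2c_positions <- t2c %||% replicate(n, integer(0), simplify = FALSE)
  df
}
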