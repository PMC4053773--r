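## ExpressionMatrix: entities x samples with a scale tag. Modeled after the
## plain-matrix containers of limma; a light S3 wrapper keeps invariants
## checkable without dragging a heavier class system through the pipeline.

VALID_SCALES <- c("counts", "rrf", "a_value", "log2fc", "rpkm", "log2rpkm")
VALID_KINDS  <- c("mirna", "mrna")

#' Construct an ExpressionMatrix
#'
#' An entities-by-samples numeric matrix tagged with the kind of entity it
#' measures (miRNA or mRNA) and the scale its values are on: raw read
#' `counts`, miRNA relative read frequencies (`rrf`), two-color microarray
#' abundance (`a_value`), microarray log2 fold-change (`log2fc`), linear
#' RPKM (`rpkm`) or log2-transformed RPKM (`log2rpkm`).
#'
#' @param values numeric matrix, rows = entities, columns = samples.
#' @param entity_ids,sample_ids unique identifiers; default to dimnames.
#' @param entity_kind `"mirna"` or `"mrna"`.
#' @param scale one of `r toString(VALID_SCALES)`.
#' @return an object of class `ExpressionMatrix` (a classed matrix with
#'   `entity_kind` and `scale` attributes).
#' @export
expression_matrix <- function(values, entity_ids = rownames(values),
                              sample_ids = colnames(values),
                              entity_kind = c("mirna", "mrna"),
                              scale = VALID_SCALES) {
  entity_kind <- match.arg(entity_kind)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(entity_ids) || is.null(sample_ids))
    stop("entity_ids and sample_ids are required")
  if (length(entity_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lists do not match matrix dimensions")
  if (anyDuplicated(entity_ids)) stop("duplicate entity ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  dimnames(values) <- list(as.character(entity_ids), as.character(sample_ids))
  if (scale == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("counts must be non-negative integers")
  }
  if (scale == "rrf") {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9) || any(values < 0) || any(values > 1))
      stop("rrf columns must be in [0,1] and sum to 1")
  }
  structure(values, class = c("ExpressionMatrix", "matrix", "array"),
            entity_kind = entity_kind, scale = scale)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s x %d samples [scale=%s]\n",
              nrow(x), attr(x, "entity_kind"), ncol(x), attr(x, "scale")))
  invisible(x)
}

em_scale <- function(x) attr(x, "scale")
em_kind  <- function(x) attr(x, "entity_kind")

## Subsetting keeps the class and tags (drop is forced off).
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, class = class(x),
            entity_kind = attr(x, "entity_kind"), scale = attr(x, "scale"))
}

#' Two-color microarray abundance (A-value)
#'
#' Abundance for a two-color array spot, log2 of the geometric mean of the
#' red and green channel intensities: `log2(sqrt(R * G))`.
#'
#' @param R,G positive linear fluorescence intensities (vectorized).
#' @return numeric A-values.
#' @export
compute_a_value <- function(R, G) {
  if (any(R <= 0) || any(G <= 0)) stop("channel intensities must be positive")
  log2(sqrt(R * G))
}

#' miRNA relative read frequency
#'
#' Divides each miRNA's read count by its sample's total read count, so every
#' column of the result sums to one.
#'
#' @param counts an `ExpressionMatrix` of miRNA counts.
#' @return an `ExpressionMatrix` with `scale = "rrf"`.
#' @export
compute_rrf <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (em_scale(counts) != "counts") stop("compute_rrf expects scale=counts")
  tot <- colSums(counts)
  bad <- tot <= 0
  if (any(bad))
    stop("all-zero sample(s): ", paste(colnames(counts)[bad], collapse = ", "))
  expression_matrix(sweep(unclass(counts), 2, tot, "/"),
                    entity_kind = em_kind(counts), scale = "rrf")
}

#' Detection filter on read counts
#'
#' Keeps entities detected with strictly more than `min_reads` reads in at
#' least `ceiling(min_sample_frac * n_samples)` samples (e.g. more than 10
#' reads in at least 5\% of samples).
#'
#' @param counts an `ExpressionMatrix` with `scale = "counts"`.
#' @param min_reads count an entity must strictly exceed.
#' @param min_sample_frac required fraction of samples, in (0, 1].
#' @return character vector of retained entity ids.
#' @export
detection_filter <- function(counts, min_reads = 10, min_sample_frac = 0.05) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (em_scale(counts) != "counts") stop("detection_filter expects scale=counts")
  if (min_sample_frac <= 0 || min_sample_frac > 1)
    stop("min_sample_frac must be in (0, 1]")
  need <- ceiling(min_sample_frac * ncol(counts))
  keep <- rowSums(unclass(counts) > min_reads) >= need
  rownames(counts)[keep]
}

#' Log-transform RPKM with per-sample zero replacement
#'
#' Within each sample, RPKM values of zero are set to the smallest non-zero
#' RPKM measured in that sample, then all values are log2-transformed.
#'
#' @param rpkm an `ExpressionMatrix` of linear RPKM values (tagged `counts`
#'   or any linear scale; values must be non-negative).
#' @return an `ExpressionMatrix` with `scale = "log2rpkm"`.
#' @export
log_transform_rpkm <- function(rpkm) {
  stopifnot(inherits(rpkm, "ExpressionMatrix"))
  v <- unclass(rpkm)
  if (any(v < 0)) stop("RPKM values must be non-negative")
  for (j in seq_len(ncol(v))) {
    nz <- v[, j] > 0
    if (!any(nz)) stop("all-zero sample: ", colnames(v)[j])
    v[!nz, j] <- min(v[nz, j])
  }
  expression_matrix(log2(v), entity_kind = em_kind(rpkm), scale = "log2rpkm")
}

#' Condense microarray probes to genes
#'
#' Probes mapping to the same gene whose pairwise Pearson correlations all
#' exceed `r_min` are averaged on the log2 fold-change scale. Probe groups
#' failing the correlation rule fall back to the single probe with the
#' highest mean signal. Probes with zero variance are excluded with a
#' warning before correlation.
#'
#' @param probe_matrix an `ExpressionMatrix` with `scale = "log2fc"`.
#' @param probe_to_gene named character vector, probe id -> gene id.
#' @param r_min pairwise correlation threshold (strict).
#' @return an `ExpressionMatrix` with gene ids as entities.
#' @export
condense_probes <- function(probe_matrix, probe_to_gene, r_min = 0.8) {
  stopifnot(inherits(probe_matrix, "ExpressionMatrix"))
  if (em_scale(probe_matrix) != "log2fc")
    stop("condense_probes expects scale=log2fc")
  probes <- rownames(probe_matrix)
  if (!all(probes %in% names(probe_to_gene)))
    stop("every probe must map to a gene")
  v <- unclass(probe_matrix)
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance probe(s): ",
            paste(probes[sds == 0], collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
    probes <- rownames(v)
  }
  genes <- unique(unname(probe_to_gene[probes]))
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  for (g in genes) {
    pr <- probes[probe_to_gene[probes] == g]
    if (length(pr) == 1L) {
      out[g, ] <- v[pr, ]
      next
    }
    cc <- stats::cor(t(v[pr, , drop = FALSE]))
    if (all(cc[upper.tri(cc)] > r_min)) {
      out[g, ] <- colMeans(v[pr, , drop = FALSE])
    } else {
      best <- pr[which.max(rowMeans(v[pr, , drop = FALSE]))]
      out[g, ] <- v[best, ]
    }
  }
  expression_matrix(out, entity_kind = "mrna", scale = "log2fc")
}
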