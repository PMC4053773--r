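## Pearson correlation of miRNA-family vs mRNA expression across patients,
## and the target-vs-background median-shift statistic: the difference of
## medians between the correlation distribution of predicted miRNA-target
## pairs and that of all remaining miRNA-mRNA pairs, tested with a
## two-sided Wilcoxon rank-sum test. A negative shift means targets are
## more anti-correlated with their miRNAs than background pairs.

#' Aggregate member miRNA expression to families
#'
#' Family expression is the sum of the member miRNAs' relative read
#' frequencies per sample (preserving the RRF scale); `"max"` takes the
#' most-expressed member instead. Families with no expressed member are
#' dropped with a warning.
#'
#' @param mirna_expr `ExpressionMatrix` of miRNA expression (rows = members).
#' @param families family table ([read_mirna_families()]).
#' @param method `"sum"` (default) or `"max"`.
#' @return `ExpressionMatrix` with family ids as entities.
#' @export
family_expression <- function(mirna_expr, families, method = c("sum", "max")) {
  method <- match.arg(method)
  rows <- lapply(seq_len(nrow(families)), function(i) {
    members <- intersect(families$member_ids[[i]], rownames(mirna_expr))
    if (!length(members)) return(NULL)
    sub <- unclass(mirna_expr)[members, , drop = FALSE]
    if (method == "sum") colSums(sub) else apply(sub, 2, max)
  })
  keep <- !vapply(rows, is.null, TRUE)
  if (any(!keep))
    warning("dropping families with no expressed member: ",
            paste(families$family_id[!keep], collapse = ", "))
  if (!any(keep)) stop("no family has an expressed member")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- families$family_id[keep]
  ## summed RRFs no longer sum to 1 over families; keep the counts tag off
  ## and mark the scale as the input's underlying measurement
  structure(m, class = c("ExpressionMatrix", "matrix", "array"),
            entity_kind = "mirna", scale = em_scale(mirna_expr))
}

#' Pearson correlations for all (family, gene) pairs
#'
#' Correlates every miRNA family with every gene over their shared samples
#' and flags pairs present in the target map. Zero-variance entities are
#' excluded (their correlation is undefined).
#'
#' @param family_expr families x samples `ExpressionMatrix`.
#' @param mrna_expr genes x samples `ExpressionMatrix`.
#' @param target_map data.frame with `family_id`, `gene_id`.
#' @return data.frame with `family_id`, `gene_id`, `r`, `n_samples`,
#'   `is_target`.
#' @export
pair_correlations <- function(family_expr, mrna_expr, target_map) {
  shared <- intersect(colnames(family_expr), colnames(mrna_expr))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  f <- unclass(family_expr)[, shared, drop = FALSE]
  g <- unclass(mrna_expr)[, shared, drop = FALSE]
  f <- f[apply(f, 1, stats::sd) > 0, , drop = FALSE]
  g <- g[apply(g, 1, stats::sd) > 0, , drop = FALSE]
  if (nrow(f) == 0 || nrow(g) == 0) stop("no entities with variance")
  r <- stats::cor(t(f), t(g))  # families x genes
  out <- data.frame(family_id = rep(rownames(r), times = ncol(r)),
                    gene_id = rep(colnames(r), each = nrow(r)),
                    r = as.vector(r),
                    n_samples = length(shared),
                    stringsAsFactors = FALSE)
  key <- paste(out$family_id, out$gene_id, sep = "\r")
  tkey <- paste(target_map$family_id, target_map$gene_id, sep = "\r")
  out$is_target <- key %in% tkey
  out
}

#' Target-vs-background correlation shift
#'
#' Difference of the medians of the target-pair and background-pair
#' correlation distributions, with a two-sided Wilcoxon rank-sum test
#' (exact when both groups have at most 50 values, normal approximation
#' with continuity correction above that).
#'
#' @param records data.frame from [pair_correlations()].
#' @param group_label label carried into the result (e.g. a subtype).
#' @return one-row data.frame: `group_label`, `median_target_r`,
#'   `median_background_r`, `median_difference`, `wilcoxon_p`,
#'   `n_target_pairs`, `n_background_pairs`.
#' @export
correlation_shift <- function(records, group_label = "all") {
  tgt <- records$r[records$is_target]
  bg  <- records$r[!records$is_target]
  if (!length(tgt) || !length(bg)) stop("both groups must be non-empty")
  exact <- length(tgt) <= 50 && length(bg) <= 50
  wt <- stats::wilcox.test(tgt, bg, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  data.frame(group_label = group_label,
             median_target_r = stats::median(tgt),
             median_background_r = stats::median(bg),
             median_difference = stats::median(tgt) - stats::median(bg),
             wilcoxon_p = wt$p.value,
             n_target_pairs = length(tgt),
             n_background_pairs = length(bg),
             stringsAsFactors = FALSE)
}

filter_by_mean <- function(expr, threshold) {
  expr[rowMeans(unclass(expr)) > threshold, , drop = FALSE]
}

#' Abundance-threshold sweep of the correlation shift
#'
#' Recomputes the correlation shift over a grid of miRNA and mRNA abundance
#' thresholds (entities kept when their mean abundance strictly exceeds the
#' threshold). Grid points at which either the target or the background
#' group is empty are marked invalid.
#'
#' @param family_expr,mrna_expr expression matrices.
#' @param target_map data.frame with `family_id`, `gene_id`.
#' @param mirna_grid,mrna_grid numeric threshold grids.
#' @return data.frame with one row per grid point: thresholds, numbers of
#'   entities kept, `median_difference`, `wilcoxon_p`, `valid`.
#' @export
threshold_sweep <- function(family_expr, mrna_expr, target_map,
                            mirna_grid, mrna_grid) {
  if (!length(mirna_grid) || !length(mrna_grid)) stop("grids must be non-empty")
  rows <- list()
  for (mt in mirna_grid) for (gt in mrna_grid) {
    fe <- filter_by_mean(family_expr, mt)
    ge <- filter_by_mean(mrna_expr, gt)
    row <- data.frame(mirna_threshold = mt, mrna_threshold = gt,
                      n_mirnas = nrow(fe), n_mrnas = nrow(ge),
                      median_difference = NA_real_, wilcoxon_p = NA_real_,
                      valid = FALSE)
    if (nrow(fe) > 0 && nrow(ge) > 0) {
      rec <- try(pair_correlations(fe, ge, target_map), silent = TRUE)
      if (!inherits(rec, "try-error") && any(rec$is_target) && any(!rec$is_target)) {
        sh <- correlation_shift(rec)
        row$median_difference <- sh$median_difference
        row$wilcoxon_p <- sh$wilcoxon_p
        row$valid <- TRUE
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Correlation shift within each molecular subtype
#'
#' @param family_expr,mrna_expr expression matrices.
#' @param target_map data.frame with `family_id`, `gene_id`.
#' @param subtypes named character vector, sample id -> subtype.
#' @param min_samples subtypes with fewer samples are skipped with a warning.
#' @return data.frame of [correlation_shift()] rows, one per eligible subtype.
#' @export
subtype_shift <- function(family_expr, mrna_expr, target_map, subtypes,
                          min_samples = 3) {
  out <- list()
  for (st in unique(subtypes)) {
    ids <- intersect(names(subtypes)[subtypes == st], colnames(family_expr))
    ids <- intersect(ids, colnames(mrna_expr))
    if (length(ids) < min_samples) {
      warning("skipping subtype ", st, ": fewer than ", min_samples, " samples")
      next
    }
    rec <- pair_correlations(family_expr[, ids], mrna_expr[, ids], target_map)
    out[[length(out) + 1L]] <- correlation_shift(rec, group_label = st)
  }
  if (!length(out)) stop("no subtype had enough samples")
  do.call(rbind, out)
}

#' Intronic miRNA / host-gene correlation by abundance
#'
#' Pearson correlation between each intronic miRNA and its host gene,
#' binned by miRNA mean abundance, with a one-sided permutation trend test
#' (correlation of bin index with pair correlation; larger-in-higher-bins
#' alternative) in the spirit of a Jonckheere-Terpstra test.
#'
#' @param mirna_expr,mrna_expr expression matrices.
#' @param host_map named character vector, miRNA id -> host gene id
#'   (multi-copy miRNAs must be absent).
#' @param n_bins number of abundance bins (quantile-based).
#' @param B trend-test permutations.
#' @param seed RNG seed.
#' @return list with `pairs` (per-pair data.frame), `bins` (per-bin mean r)
#'   and `trend_p`.
#' @export
intronic_host_analysis <- function(mirna_expr, mrna_expr, host_map,
                                   n_bins = 4, B = 999, seed = NULL) {
  mir <- intersect(names(host_map), rownames(mirna_expr))
  mir <- mir[host_map[mir] %in% rownames(mrna_expr)]
  if (!length(mir)) stop("no mapped (miRNA, host) pairs present")
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  r <- vapply(mir, function(m) {
    stats::cor(unclass(mirna_expr)[m, shared], unclass(mrna_expr)[host_map[m], shared])
  }, 0)
  ab <- rowMeans(unclass(mirna_expr)[mir, shared, drop = FALSE])
  n_bins <- min(n_bins, length(unique(ab)))
  bin <- if (n_bins <= 1) rep(1L, length(ab)) else
    as.integer(cut(rank(ab, ties.method = "first"),
                   breaks = n_bins, labels = FALSE))
  pairs <- data.frame(mirna_id = mir, host_gene_id = unname(host_map[mir]),
                      r = r, mean_abundance = ab, bin = bin,
                      stringsAsFactors = FALSE)
  bins <- stats::aggregate(list(mean_r = pairs$r, n = rep(1, nrow(pairs))),
                           by = list(bin = pairs$bin),
                           FUN = function(x) sum(x) / length(x))
  bins$n <- as.integer(stats::aggregate(rep(1, nrow(pairs)),
                                        by = list(bin = pairs$bin), FUN = sum)$x)
  obs <- stats::cor(pairs$bin, pairs$r)
  trend_p <- if (is.na(obs)) NA_real_ else run_seeded(seed, {
    null <- replicate(B, stats::cor(pairs$bin, sample(pairs$r)))
    empirical_pvalue(obs, null)
  })
  list(pairs = pairs, bins = bins, trend_p = trend_p)
}

#' Spearman rank concordance of two rankings
#'
#' @param ranking_a,ranking_b named numeric vectors (score or rank); only
#'   shared names are used; ties receive average ranks.
#' @return list with `rho`, `p`, `n_shared`.
#' @export
rank_concordance <- function(ranking_a, ranking_b) {
  shared <- intersect(names(ranking_a), names(ranking_b))
  if (length(shared) < 3) stop("need at least 3 shared items")
  ct <- suppressWarnings(
    stats::cor.test(ranking_a[shared], ranking_b[shared],
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_shared = length(shared))
}
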