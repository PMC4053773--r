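## Equal-weight rank aggregation of per-family evidence p-values, miRNA
## regulatory-activity and tumor-phenotype rankings, and Cox-based target
## prognostic signatures.

#' Combine evidence p-values into an equal-weight mean-rank score
#'
#' Within each evidence column, families are ranked ascending by p-value
#' (ties receive average ranks; missing values the worst rank). The
#' combined score is the unweighted mean rank across columns. Significance
#' is assessed by `B` permutations that independently shuffle each column's
#' values across families; a family's rank-test p is the add-one fraction
#' of permutations in which its combined score is at least as small as
#' observed.
#'
#' @param evidence numeric matrix, families x evidence sources (p-values;
#'   `NA` allowed). Row names identify families.
#' @param B number of permutations.
#' @param seed RNG seed.
#' @return data.frame sorted by combined score: `family_id`, per-source
#'   ranks (`rank_<col>`), `combined_score`, `rank_test_p`.
#' @export
rank_evidence <- function(evidence, B = 9999, seed = NULL) {
  evidence <- as.matrix(evidence)
  if (is.null(rownames(evidence))) stop("evidence needs family row names")
  if (nrow(evidence) < 2) stop("need at least 2 families")
  all_na <- rowSums(!is.na(evidence)) == 0
  if (any(all_na)) {
    warning("excluding families with no evidence: ",
            paste(rownames(evidence)[all_na], collapse = ", "))
    evidence <- evidence[!all_na, , drop = FALSE]
  }
  n <- nrow(evidence)
  rank_col <- function(p) {
    r <- rank(p, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- n  # missing evidence gets the worst rank
    r
  }
  ranks <- apply(evidence, 2, rank_col)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = ncol(evidence))
  score <- rowMeans(ranks)
  perm_p <- run_seeded(seed, {
    hits <- numeric(n)
    for (b in seq_len(B)) {
      perm <- apply(ranks, 2, sample)
      hits <- hits + (rowMeans(perm) <= score)
    }
    (1 + hits) / (B + 1)
  })
  out <- data.frame(family_id = rownames(evidence), ranks,
                    combined_score = score, rank_test_p = perm_p,
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out)[1 + seq_len(ncol(ranks))] <-
    paste0("rank_", colnames(evidence) %||% seq_len(ncol(ranks)))
  out <- out[order(out$combined_score, out$family_id), ]
  rownames(out) <- NULL
  out
}

#' Rank miRNA regulatory activity from three evidence sources
#'
#' Builds the three-column evidence matrix for each family — (1) global-test
#' p of the family's expression against its MP-PCLIP target expression,
#' (2) the smallest global-test p over gene sets containing at least one
#' MP-PCLIP target of the family, (3) global-test p against the cancer-gene
#' set — and aggregates with [rank_evidence()]. Families with no MP-PCLIP
#' target are excluded.
#'
#' @param family_expr,mrna_expr expression matrices over the same samples.
#' @param mp_pclip_map data.frame with `family_id`, `gene_id`.
#' @param gene_sets named list of gene sets (pathways).
#' @param cgc_set character vector: the cancer-gene set.
#' @param B permutations for both the global tests and the rank test.
#' @param seed RNG seed.
#' @return list with `ranking` ([rank_evidence()] output) and `evidence`
#'   (the p-value matrix).
#' @export
activity_ranking <- function(family_expr, mrna_expr, mp_pclip_map, gene_sets,
                             cgc_set, B = 999, seed = NULL) {
  shared <- intersect(colnames(family_expr), colnames(mrna_expr))
  fe <- unclass(family_expr)[, shared, drop = FALSE]
  ge <- unclass(mrna_expr)[, shared, drop = FALSE]
  fams <- rownames(fe)
  has_target <- vapply(fams, function(f) {
    length(intersect(mp_pclip_map$gene_id[mp_pclip_map$family_id == f],
                     rownames(ge))) > 0
  }, TRUE)
  if (any(!has_target))
    message("excluding families with no expressed MP-PCLIP target: ",
            paste(fams[!has_target], collapse = ", "))
  fams <- fams[has_target]
  if (!length(fams)) stop("no family has an expressed MP-PCLIP target")
  seeds <- run_seeded(seed, sample.int(.Machine$integer.max, 3))
  assoc <- associate_sets(family_expr[fams, , drop = FALSE], mrna_expr,
                          gene_sets, mp_pclip_map, B = B, seed = seeds[1])
  cgc <- intersect(cgc_set, rownames(ge))
  if (!length(cgc)) stop("cancer-gene set has no expressed member")
  gt_seeds <- run_seeded(seeds[2], sample.int(.Machine$integer.max, 2 * length(fams)))
  evidence <- t(vapply(seq_along(fams), function(i) {
    f <- fams[i]
    tgt <- intersect(mp_pclip_map$gene_id[mp_pclip_map$family_id == f],
                     rownames(ge))
    p_target <- global_test(fe[f, ], t(ge[tgt, , drop = FALSE]),
                            model_kind = "linear", B = B,
                            seed = gt_seeds[2 * i - 1])$p_perm
    sub <- assoc[assoc$family_id == f & assoc$contains_mp_pclip, , drop = FALSE]
    p_pathway <- if (nrow(sub)) min(sub$p) else NA_real_
    p_cgc <- global_test(fe[f, ], t(ge[cgc, , drop = FALSE]),
                         model_kind = "linear", B = B,
                         seed = gt_seeds[2 * i])$p_perm
    c(target = p_target, pathway = p_pathway, cancer_genes = p_cgc)
  }, numeric(3)))
  rownames(evidence) <- fams
  list(ranking = rank_evidence(evidence, B = B, seed = seeds[3]),
       evidence = evidence)
}

#' Rank miRNA association with tumor phenotypes
#'
#' For each family, the covariate set is its own expression together with
#' its MP-PCLIP target expression; one global test is run per phenotype:
#' logistic for lymph-node status and lymphovascular invasion, multinomial
#' for tumor size class and grade, Cox for time to metastasis and overall
#' survival. Phenotype columns with no variation are dropped. The resulting
#' per-family p-value matrix is aggregated with [rank_evidence()].
#'
#' @param family_expr,mrna_expr expression matrices.
#' @param mp_pclip_map data.frame with `family_id`, `gene_id`.
#' @param annotation sample annotation ([read_sample_annotation()]).
#' @param B permutations.
#' @param seed RNG seed.
#' @param include_mirna if `FALSE`, the family's own expression is left out
#'   of the covariate set.
#' @return list with `ranking` and `evidence`.
#' @export
phenotype_ranking <- function(family_expr, mrna_expr, mp_pclip_map, annotation,
                              B = 999, seed = NULL, include_mirna = TRUE) {
  shared <- intersect(intersect(colnames(family_expr), colnames(mrna_expr)),
                      annotation$sample_id)
  fe <- unclass(family_expr)[, shared, drop = FALSE]
  ge <- unclass(mrna_expr)[, shared, drop = FALSE]
  ann <- annotation[match(shared, annotation$sample_id), , drop = FALSE]
  phenos <- list(
    lymph_node = list(col = "lymph_node_positive", kind = "logistic"),
    lvi = list(col = "lymphovascular_invasion", kind = "logistic"),
    tumor_size = list(col = "tumor_size_class", kind = "multinomial"),
    grade = list(col = "grade", kind = "multinomial"),
    metastasis = list(col = "time_to_metastasis", kind = "cox",
                      event = "metastasis_event"),
    survival = list(col = "overall_survival", kind = "cox",
                    event = "survival_event"))
  fams <- rownames(fe)
  fams <- fams[vapply(fams, function(f)
    length(intersect(mp_pclip_map$gene_id[mp_pclip_map$family_id == f],
                     rownames(ge))) > 0, TRUE)]
  if (!length(fams)) stop("no family has an expressed MP-PCLIP target")
  seeds <- run_seeded(seed, sample.int(.Machine$integer.max,
                                       length(fams) * length(phenos) + 1))
  evid <- matrix(NA_real_, length(fams), length(phenos),
                 dimnames = list(fams, names(phenos)))
  si <- 0L
  for (f in fams) {
    tgt <- intersect(mp_pclip_map$gene_id[mp_pclip_map$family_id == f],
                     rownames(ge))
    X <- t(ge[tgt, , drop = FALSE])
    if (include_mirna) X <- cbind(mirna = fe[f, ], X)
    for (ph in names(phenos)) {
      si <- si + 1L
      spec <- phenos[[ph]]
      if (!spec$col %in% names(ann)) next
      y <- ann[[spec$col]]
      keep <- !is.na(y)
      ev <- NULL
      if (spec$kind == "cox") {
        if (!spec$event %in% names(ann)) next
        ev <- ann[[spec$event]]
        keep <- keep & !is.na(ev)
      }
      if (sum(keep) < 3) next
      yk <- y[keep]
      if (length(unique(yk)) < 2) next  # no variation
      p <- try(global_test(yk, X[keep, , drop = FALSE],
                           model_kind = spec$kind, B = B, seed = seeds[si],
                           event = if (is.null(ev)) NULL else ev[keep])$p_perm,
               silent = TRUE)
      if (!inherits(p, "try-error")) evid[f, ph] <- p
    }
  }
  evid <- evid[, colSums(!is.na(evid)) > 0, drop = FALSE]
  if (ncol(evid) == 0) stop("no phenotype column could be tested")
  list(ranking = rank_evidence(evid, B = B, seed = seeds[length(seeds)]),
       evidence = evid)
}

#' Prognostic signature test for one miRNA family's targets
#'
#' Cox-mode global test of the family's expression plus its target
#' expression against survival. In adjusted mode the null-model residuals
#' are martingale residuals of a Cox model on the supplied clinical
#' covariates, so the test asks whether the signature explains survival
#' beyond the clinical model.
#'
#' @param family_id family to test.
#' @param family_expr,mrna_expr expression matrices.
#' @param target_map data.frame with `family_id`, `gene_id`.
#' @param time,event survival times and 0/1 event indicators, named by
#'   sample or aligned with the expression columns.
#' @param clinical optional data.frame of clinical covariates (rows aligned
#'   with samples) for adjusted mode.
#' @param B permutations.
#' @param seed RNG seed.
#' @param min_events minimum number of events required.
#' @return list with `gt` (`gt_result`), `genes` (the signature gene list),
#'   `adjusted` flag.
#' @export
survival_signature <- function(family_id, family_expr, mrna_expr, target_map,
                               time, event, clinical = NULL, B = 999,
                               seed = NULL, min_events = 10) {
  shared <- intersect(colnames(family_expr), colnames(mrna_expr))
  if (!is.null(names(time))) {
    shared <- intersect(shared, names(time))
    time <- time[shared]; event <- event[shared]
    if (!is.null(clinical)) clinical <- clinical[shared, , drop = FALSE]
  }
  if (sum(event) < min_events) stop("fewer than ", min_events, " events")
  tgt <- intersect(target_map$gene_id[target_map$family_id == family_id],
                   rownames(mrna_expr))
  if (!length(tgt)) stop("family has no expressed target")
  X <- cbind(mirna = unclass(family_expr)[family_id, shared],
             t(unclass(mrna_expr)[tgt, shared, drop = FALSE]))
  if (is.null(clinical)) {
    gt <- global_test(time, X, model_kind = "cox", B = B, seed = seed,
                      event = event)
    adjusted <- FALSE
  } else {
    if (anyNA(clinical)) stop("missing clinical covariates in adjusted mode")
    fit <- survival::coxph(survival::Surv(time, event) ~ .,
                           data = as.data.frame(clinical))
    r <- stats::residuals(fit, type = "martingale")
    gt <- global_test(r, X, model_kind = "linear", B = B, seed = seed)
    adjusted <- TRUE
  }
  list(gt = gt, genes = c(family_id, tgt), adjusted = adjusted)
}
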