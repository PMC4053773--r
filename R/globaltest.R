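## Permutation-calibrated global test of gene-set association. For a
## response y and a standardized covariate matrix X (samples x m), the
## statistic is the mean squared score of the covariates against the
## null-model residuals r:
##
##   Q = (1/m) * sum_j (x_j' r)^2
##
## with r the residuals of the intercept-only model for the response kind:
## centered response (linear), y - mean(y) (logistic), stacked one-vs-rest
## indicator residuals (multinomial), or null martingale residuals from the
## Nelson-Aalen baseline (Cox). Significance comes from permuting the
## residual vector across samples, with the add-one empirical p-value, so
## the test is exact under exchangeability regardless of the response
## distribution. Q is invariant to covariate order and to sign flips of any
## standardized covariate.

null_residuals <- function(response, model_kind, event = NULL) {
  switch(model_kind,
    linear = {
      y <- as.numeric(response)
      cbind(y - mean(y))
    },
    logistic = {
      y <- as.numeric(response)
      if (!all(y %in% c(0, 1))) stop("logistic response must be 0/1")
      if (length(unique(y)) < 2) stop("logistic response has a single class")
      cbind(y - mean(y))
    },
    multinomial = {
      f <- factor(response)
      if (nlevels(f) < 2) stop("multinomial response has a single class")
      ind <- stats::model.matrix(~ f - 1)
      sweep(ind, 2, colMeans(ind))  # one-vs-rest residuals, stacked as columns
    },
    cox = {
      time <- as.numeric(response)
      if (is.null(event)) stop("cox response needs an event indicator")
      if (any(time < 0)) stop("survival times must be non-negative")
      if (sum(event) < 1) stop("no events")
      fit <- survival::coxph(survival::Surv(time, event) ~ 1)
      cbind(stats::residuals(fit, type = "martingale"))
    },
    stop("unknown model_kind: ", model_kind))
}

standardize_covariates <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance covariate(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no covariates with variance")
  scale(X)
}

gt_statistic <- function(Xs, R) {
  ## R: samples x c residual matrix (c > 1 for multinomial)
  S <- crossprod(Xs, R)              # m x c
  sum(S^2) / ncol(Xs)
}

#' Global test of a covariate set against a response
#'
#' Tests whether a group of covariates (for example the expression of a
#' gene set) is jointly associated with a response: a continuous variable,
#' a binary class, a multi-level class, or censored survival. See the file
#' header for the statistic; the p-value is an add-one permutation p over
#' `B` permutations of the sample labels.
#'
#' @param response numeric vector (linear), 0/1 (logistic), factor-like
#'   (multinomial) or survival times (cox, with `event`).
#' @param X covariate matrix, samples x covariates; standardized internally.
#' @param model_kind `"linear"`, `"logistic"`, `"multinomial"` or `"cox"`.
#' @param B number of permutations (ignored when `exhaustive = TRUE`).
#' @param seed RNG seed.
#' @param event 0/1 event indicator for `model_kind = "cox"`.
#' @param exhaustive if `TRUE` enumerate all n! permutations (n <= 8) and
#'   report the exact permutation p (identity included, no add-one).
#' @return object of class `gt_result`: list with `Q`, `p_perm`, `B`,
#'   `n_covariates`, `model_kind`, `n_samples`.
#' @export
global_test <- function(response, X, model_kind = c("linear", "logistic",
                                                    "multinomial", "cox"),
                        B = 9999, seed = NULL, event = NULL,
                        exhaustive = FALSE) {
  model_kind <- match.arg(model_kind)
  Xs <- standardize_covariates(X)
  n <- nrow(Xs)
  if (n < 3) stop("need at least 3 samples")
  if (length(response) != n)
    stop("response length does not match covariate rows")
  R <- null_residuals(response, model_kind, event)
  Q <- gt_statistic(Xs, R)
  if (exhaustive) {
    if (n > 8) stop("exhaustive permutation limited to n <= 8")
    perms <- all_permutations(n)
    Qb <- vapply(seq_len(nrow(perms)), function(i)
      gt_statistic(Xs, R[perms[i, ], , drop = FALSE]), 0)
    p <- mean(Qb >= Q - 1e-12)
    B_used <- nrow(perms)
  } else {
    Qb <- run_seeded(seed, {
      vapply(seq_len(B), function(b)
        gt_statistic(Xs, R[sample.int(n), , drop = FALSE]), 0)
    })
    p <- empirical_pvalue(Q, Qb)
    B_used <- B
  }
  structure(list(Q = Q, p_perm = p, B = B_used,
                 n_covariates = ncol(Xs), model_kind = model_kind,
                 n_samples = n),
            class = "gt_result")
}

#' @export
print.gt_result <- function(x, ...) {
  cat(sprintf("Global test (%s): Q = %.4g, p = %.4g (m = %d, n = %d, B = %d)\n",
              x$model_kind, x$Q, x$p_perm, x$n_covariates, x$n_samples, x$B))
  invisible(x)
}

#' Associate miRNA families with gene sets via the global test
#'
#' One global test per (family, gene set): response = family expression
#' across samples, covariates = expression of the set members present in
#' the mRNA matrix. BH correction is applied across sets within each
#' family. Each association is flagged when the set contains at least one
#' MP-PCLIP target of the family, and the Pearson correlation signs of
#' those targets with the family are attached.
#'
#' @param family_expr families x samples `ExpressionMatrix`.
#' @param mrna_expr genes x samples `ExpressionMatrix`.
#' @param gene_sets named list of gene id vectors (e.g. from [read_gmt()]).
#' @param mp_pclip_map data.frame with `family_id`, `gene_id`.
#' @param B permutations per test.
#' @param seed RNG seed.
#' @return data.frame with one row per (family, set): `family_id`,
#'   `gene_set_id`, `Q`, `p`, `bh_q`, `n_covariates`, `contains_mp_pclip`,
#'   `mp_pclip_target_signs` (comma-separated `+`/`-`).
#' @export
associate_sets <- function(family_expr, mrna_expr, gene_sets, mp_pclip_map,
                           B = 999, seed = NULL) {
  shared <- intersect(colnames(family_expr), colnames(mrna_expr))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  fe <- unclass(family_expr)[, shared, drop = FALSE]
  ge <- unclass(mrna_expr)[, shared, drop = FALSE]
  rows <- list()
  seeds <- run_seeded(seed, sample.int(.Machine$integer.max,
                                       nrow(fe) * length(gene_sets)))
  si <- 0L
  for (fam in rownames(fe)) {
    fam_rows <- list()
    for (gs in names(gene_sets)) {
      si <- si + 1L
      members <- intersect(gene_sets[[gs]], rownames(ge))
      if (!length(members)) {
        warning("skipping set ", gs, ": no expressed member")
        next
      }
      gt <- global_test(fe[fam, ], t(ge[members, , drop = FALSE]),
                        model_kind = "linear", B = B, seed = seeds[si])
      tgt <- mp_pclip_map$gene_id[mp_pclip_map$family_id == fam]
      hit <- intersect(members, tgt)
      signs <- if (length(hit))
        paste(ifelse(stats::cor(fe[fam, ], t(ge[hit, , drop = FALSE])) >= 0,
                     "+", "-"), collapse = ",") else ""
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        family_id = fam, gene_set_id = gs, Q = gt$Q, p = gt$p_perm,
        n_covariates = gt$n_covariates,
        contains_mp_pclip = length(hit) > 0,
        mp_pclip_target_signs = signs, stringsAsFactors = FALSE)
    }
    if (length(fam_rows)) {
      fr <- do.call(rbind, fam_rows)
      fr$bh_q <- stats::p.adjust(fr$p, method = "BH")
      rows[[length(rows) + 1L]] <- fr
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare association p-values with and without MP-PCLIP support
#'
#' One-sided Welch t-test on -log10 p-values, testing whether associations
#' whose gene set contains an MP-PCLIP target have smaller p-values (larger
#' -log10 p) than those that do not.
#'
#' @param p_with_flag,p_without_flag p-value vectors (each length >= 2).
#' @return list with `t`, `p`, `df`.
#' @export
compare_pvalue_groups <- function(p_with_flag, p_without_flag) {
  if (length(p_with_flag) < 2 || length(p_without_flag) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(-log10(p_with_flag), -log10(p_without_flag),
                      alternative = "greater", var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}
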