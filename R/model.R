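## "PAR-CLIP-like" interaction classifier: assemble labeled miRNA-target
## pairs from PAR-CLIP evidence and prediction-table features, fit a
## binomial elastic net (glmnet), evaluate AUC/PPV, and form the MP-PCLIP
## set as the union of biochemical and model-predicted interactions.

FEATURE_NAMES <- c("aggregate_pct", "total_context_score",
                   "n_conserved_sites", "n_nonconserved_sites",
                   "n_cons_7m8", "n_cons_7a1", "n_cons_8mer",
                   "n_noncons_7m8", "n_noncons_7a1", "n_noncons_8mer",
                   "mirna_mean_abundance", "mirna_variance",
                   "mrna_mean_abundance", "mrna_variance",
                   "interaction_signed", "interaction_unsigned")

pair_key <- function(f, g) paste(f, g, sep = "\r")

#' Assemble and label candidate miRNA-target pairs
#'
#' Candidate pairs are prediction-table rows whose family and gene pass the
#' abundance thresholds and whose gene is AGO2-crosslinked (owns at least
#' one retained cluster). A pair is labeled positive when a PAR-CLIP seed
#' site supports it, negative otherwise — so the negatives are crosslinked
#' but not seed-matched. Expression features (mean and variance per family
#' and gene, and the two interaction terms) are taken from the supplied
#' matrices; the signed interaction term multiplies the unsigned one by the
#' sign of the gene's mean log2 fold-change when available and equals the
#' unsigned term otherwise.
#'
#' @param predictions prediction table ([read_target_predictions()]).
#' @param parclip_pairs data.frame with `family_id`, `gene_id` of
#'   PAR-CLIP seed-matched interactions.
#' @param crosslinked_genes character vector of genes with >= 1 retained
#'   cluster.
#' @param family_expr,mrna_expr expression matrices (threshold-filtered).
#' @param log2fc_sign optional named vector of per-gene signs of mean log2
#'   fold-change.
#' @return data.frame of labeled pairs: ids, the 16 features, `label`.
#' @export
assemble_and_label <- function(predictions, parclip_pairs, crosslinked_genes,
                               family_expr, mrna_expr, log2fc_sign = NULL) {
  feats <- build_pair_features(predictions, family_expr, mrna_expr, log2fc_sign)
  cand <- feats[feats$gene_id %in% crosslinked_genes, , drop = FALSE]
  if (nrow(cand) == 0) stop("no candidate pairs after filtering")
  cand$label <- as.integer(pair_key(cand$family_id, cand$gene_id) %in%
                             pair_key(parclip_pairs$family_id, parclip_pairs$gene_id))
  if (all(cand$label == 1) || all(cand$label == 0))
    stop("both positive and negative pairs are required to fit the model")
  rownames(cand) <- NULL
  cand
}

#' Pair features for all expressed prediction-table pairs
#'
#' Restricts the prediction table to pairs whose family and gene are
#' present in the (threshold-filtered) expression matrices and attaches the
#' expression-derived features. Unlike [assemble_and_label()] this keeps
#' pairs without crosslink evidence — those never enter training but are
#' scored by the fitted model, which is what makes additional
#' "PAR-CLIP-like" predictions possible.
#'
#' @inheritParams assemble_and_label
#' @return data.frame of pairs with the 16 feature columns.
#' @export
build_pair_features <- function(predictions, family_expr, mrna_expr,
                                log2fc_sign = NULL) {
  keep <- predictions$family_id %in% rownames(family_expr) &
    predictions$gene_id %in% rownames(mrna_expr)
  cand <- predictions[keep, , drop = FALSE]
  if (nrow(cand) == 0) stop("no expressed pairs")
  fm <- unclass(family_expr); gm <- unclass(mrna_expr)
  mir_mean <- rowMeans(fm); mir_var <- apply(fm, 1, stats::var)
  rna_mean <- rowMeans(gm); rna_var <- apply(gm, 1, stats::var)
  cand$mirna_mean_abundance <- mir_mean[cand$family_id]
  cand$mirna_variance <- mir_var[cand$family_id]
  cand$mrna_mean_abundance <- rna_mean[cand$gene_id]
  cand$mrna_variance <- rna_var[cand$gene_id]
  cand$interaction_unsigned <- cand$mirna_mean_abundance * cand$mrna_mean_abundance
  sgn <- if (is.null(log2fc_sign)) rep(1, nrow(cand)) else
    log2fc_sign[cand$gene_id]
  cand$interaction_signed <- cand$interaction_unsigned * sgn
  rownames(cand) <- NULL
  cand
}

#' Stratified train/test split
#'
#' @param pairs labeled pairs ([assemble_and_label()]).
#' @param train_fraction fraction per class assigned to training.
#' @param seed RNG seed (split is deterministic given the seed).
#' @return `pairs` with an added `split` column (`train`/`test`).
#' @export
split_train_test <- function(pairs, train_fraction = 0.5, seed = NULL) {
  if (min(table(pairs$label)) < 2) stop("each class needs at least 2 pairs")
  split <- rep("test", nrow(pairs))
  run_seeded(seed, {
    for (cl in unique(pairs$label)) {
      idx <- which(pairs$label == cl)
      n_train <- round(train_fraction * length(idx))
      split[sample(idx, n_train)] <- "train"
    }
    split
  }) -> pairs$split
  pairs
}

#' Fit the elastic-net interaction classifier
#'
#' Binomial elastic net over the 16 pair features, standardized to zero
#' mean / unit variance (the transform is stored in the model). With a
#' `lambda_grid` of length one the model is fit at that penalty; otherwise
#' the penalty minimizing 10-fold cross-validated deviance is chosen. The
#' LASSO/ridge mixing parameter `alpha` defaults to 0.5.
#'
#' @param pairs labeled pairs; only rows with `split == "train"` are used
#'   when a `split` column is present.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param lambda_grid optional penalty grid (glmnet chooses its own path
#'   when `NULL`).
#' @param cv_folds folds for cross-validation.
#' @param seed RNG seed for fold assignment.
#' @return object of class `mirti_enet`.
#' @export
fit_elastic_net <- function(pairs, alpha = 0.5, lambda_grid = NULL,
                            cv_folds = 10, seed = NULL) {
  train <- if ("split" %in% names(pairs)) pairs[pairs$split == "train", ] else pairs
  X <- as.matrix(train[, FEATURE_NAMES])
  y <- train$label
  if (length(unique(y)) < 2) stop("training set has a single class")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  drop <- sdv == 0
  if (any(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(FEATURE_NAMES[drop], collapse = ", "))
    sdv[drop] <- 1  # kept in the transform; coefficient forced to zero below
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xs <- Xs[, !drop, drop = FALSE]
  if (!is.null(lambda_grid) && length(lambda_grid) == 1) {
    fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = alpha,
                          lambda = lambda_grid, standardize = FALSE,
                          thresh = 1e-12)
    lambda <- lambda_grid
  } else {
    cv <- run_seeded(seed, glmnet::cv.glmnet(Xs, y, family = "binomial",
                                             alpha = alpha,
                                             lambda = lambda_grid,
                                             nfolds = cv_folds,
                                             standardize = FALSE))
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
  }
  beta_std <- stats::setNames(rep(0, length(FEATURE_NAMES)), FEATURE_NAMES)
  co <- as.matrix(stats::coef(fit, s = lambda))
  beta_std[rownames(co)[-1]] <- co[-1, 1]
  intercept_std <- co[1, 1]
  ## back-transform to the raw feature scale
  beta_raw <- beta_std / sdv
  intercept_raw <- intercept_std - sum(beta_std * mu / sdv)
  structure(list(coefficients_std = beta_std, intercept_std = intercept_std,
                 coefficients = beta_raw, intercept = intercept_raw,
                 alpha = alpha, lambda = lambda,
                 feature_means = mu, feature_sds = sdv,
                 features = FEATURE_NAMES, cv_seed = seed),
            class = "mirti_enet")
}

#' @export
print.mirti_enet <- function(x, ...) {
  nz <- sum(x$coefficients_std != 0)
  cat(sprintf("Elastic-net interaction model: alpha=%.2f lambda=%.4g, %d/%d nonzero features\n",
              x$alpha, x$lambda, nz, length(x$features)))
  invisible(x)
}

#' Posterior probabilities from the fitted model
#' @param object a `mirti_enet` model.
#' @param newdata data.frame carrying the 16 feature columns.
#' @param ... unused.
#' @return numeric posteriors in \[0, 1\].
#' @export
predict.mirti_enet <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features])
  eta <- drop(X %*% object$coefficients) + object$intercept
  1 / (1 + exp(-eta))
}

#' Evaluate the classifier
#'
#' AUC via the rank statistic (midranks for ties) on training and test
#' splits, plus the positive-predictive-value curve PPV(c) = TP / (TP + FP)
#' among pairs with posterior >= c, and the FDR (1 - PPV) at the working
#' cutoff.
#'
#' @param model `mirti_enet` model.
#' @param pairs labeled pairs with a `split` column.
#' @param cutoffs grid of posterior cutoffs for the PPV curve.
#' @param working_cutoff cutoff at which `fdr_at_cutoff` is reported.
#' @return list with `auc_train`, `auc_test`, `ppv_curve` (data.frame),
#'   `fdr_at_cutoff`.
#' @export
evaluate_model <- function(model, pairs, cutoffs = seq(0, 1, by = 0.05),
                           working_cutoff = 0.5) {
  post <- predict(model, pairs)
  split <- pairs$split %||% rep("test", nrow(pairs))
  auc_for <- function(sel) {
    if (length(unique(pairs$label[sel])) < 2)
      stop("evaluation split has a single class")
    rank_auc(post[sel], pairs$label[sel])
  }
  ppv <- vapply(cutoffs, function(cc) {
    sel <- post >= cc
    if (!any(sel)) return(NA_real_)
    sum(pairs$label[sel] == 1) / sum(sel)
  }, 0)
  ppv_at <- function(cc) {
    sel <- post >= cc
    if (!any(sel)) NA_real_ else sum(pairs$label[sel] == 1) / sum(sel)
  }
  list(auc_train = if (any(split == "train")) auc_for(split == "train") else NA_real_,
       auc_test = if (any(split == "test")) auc_for(split == "test") else NA_real_,
       ppv_curve = data.frame(cutoff = cutoffs, ppv = ppv),
       fdr_at_cutoff = 1 - ppv_at(working_cutoff))
}

#' Select the MP-PCLIP interaction set
#'
#' Scores all candidate predictions (including pairs without crosslink
#' support, which never entered training) and takes the union of the
#' biochemical PAR-CLIP pairs with the model-predicted pairs at the
#' posterior cutoff. Each pair is tagged `parclip`, `model` or `both`.
#'
#' @param model `mirti_enet` model.
#' @param candidates data.frame with the 16 feature columns plus
#'   `family_id`, `gene_id`.
#' @param parclip_pairs data.frame with `family_id`, `gene_id`.
#' @param cutoff posterior cutoff (default 0.5).
#' @return data.frame: `family_id`, `gene_id`, `posterior` (`NA` for
#'   PAR-CLIP-only pairs absent from the candidates), `source`; with
#'   attribute `counts` = c(n_predicted, n_parclip_supported, n_additional).
#' @export
select_mp_pclip <- function(model, candidates, parclip_pairs, cutoff = 0.5) {
  post <- predict(model, candidates)
  pred <- candidates[post >= cutoff, c("family_id", "gene_id"), drop = FALSE]
  pred$posterior <- post[post >= cutoff]
  pk <- pair_key(parclip_pairs$family_id, parclip_pairs$gene_id)
  dk <- pair_key(pred$family_id, pred$gene_id)
  pred$source <- ifelse(dk %in% pk, "both", "model")
  only_parclip <- parclip_pairs[!(pk %in% dk), c("family_id", "gene_id"), drop = FALSE]
  if (nrow(only_parclip)) {
    only_parclip$posterior <- NA_real_
    only_parclip$source <- "parclip"
  } else {
    only_parclip <- data.frame(family_id = character(0), gene_id = character(0),
                               posterior = numeric(0), source = character(0))
  }
  out <- rbind(pred, only_parclip)
  rownames(out) <- NULL
  attr(out, "counts") <- c(n_predicted = nrow(pred),
                           n_parclip_supported = sum(pred$source == "both"),
                           n_additional = sum(pred$source == "model"))
  out
}

#' Univariate feature-label association
#'
#' Point-biserial (Pearson) correlation of each standardized feature with
#' the binary label, with BH-corrected p-values. Zero-variance features are
#' reported as `NA`.
#'
#' @param pairs labeled pairs.
#' @return data.frame with `feature`, `correlation`, `p`, `bh_q`.
#' @export
univariate_feature_assoc <- function(pairs) {
  out <- do.call(rbind, lapply(FEATURE_NAMES, function(f) {
    x <- pairs[[f]]
    if (stats::sd(x) == 0)
      return(data.frame(feature = f, correlation = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, pairs$label)
    data.frame(feature = f, correlation = unname(ct$estimate), p = ct$p.value)
  }))
  out$bh_q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
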