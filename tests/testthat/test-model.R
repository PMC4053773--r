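# Prediction-table fixture: n rows with baseline feature values.
make_pred_fixture <- function(family_id, gene_id) {
  n <- length(family_id)
  data.frame(family_id = family_id, gene_id = gene_id,
             aggregate_pct = rep(0.3, n), total_context_score = rep(-0.2, n),
             n_cons_7m8 = 0L, n_cons_7a1 = 0L, n_cons_8mer = 0L,
             n_noncons_7m8 = 0L, n_noncons_7a1 = 0L, n_noncons_8mer = 0L,
             n_conserved_sites = 0L, n_nonconserved_sites = 0L,
             conserved_flag = 0L, stringsAsFactors = FALSE)
}

expr_fixture <- function(families, genes, n = 12) {
  set.seed(90)
  fe <- structure(matrix(rlnorm(length(families) * n, -2, 0.5),
                         length(families), n,
                         dimnames = list(families, paste0("s", 1:n))),
                  class = c("ExpressionMatrix", "matrix", "array"),
                  entity_kind = "mirna", scale = "rrf")
  ge <- structure(matrix(rnorm(length(genes) * n, 8, 1), length(genes), n,
                         dimnames = list(genes, paste0("s", 1:n))),
                  class = c("ExpressionMatrix", "matrix", "array"),
                  entity_kind = "mrna", scale = "a_value")
  list(fe = fe, ge = ge)
}

test_that("pair assembly keeps crosslinked expressed pairs and labels by seed match", {
  preds <- make_pred_fixture(
    family_id = rep(c("fA", "fB", "fC"), each = 4),
    gene_id = rep(c("g1", "g2", "g3", "gX"), 3))
  ex <- expr_fixture(c("fA", "fB"), c("g1", "g2", "g3"))
  crosslinked <- c("g1", "g2")
  parclip <- data.frame(family_id = c("fA", "fA", "fB"),
                        gene_id = c("g1", "g2", "g1"))
  pairs <- assemble_and_label(preds, parclip, crosslinked, ex$fe, ex$ge)
  # fC unexpressed (4 rows gone is wrong: fC rows have expressed genes but
  # family missing); gX unexpressed; g3 expressed but not crosslinked.
  # Remaining: fA/fB x g1/g2 = 4 pairs... hand count:
  # excluded: all fC (4), gX rows for fA/fB (2), g3 rows for fA/fB (2) = 8
  expect_equal(nrow(pairs), 4)
  expect_equal(sum(pairs$label), 3)   # fA-g1, fA-g2, fB-g1
  expect_equal(sum(pairs$label == 0), 1)  # fB-g2 crosslinked, no seed match
  expect_true(all(c(mirti:::FEATURE_NAMES) %in% names(pairs)))
  expect_error(assemble_and_label(preds, parclip, "gX", ex$fe, ex$ge))
})

test_that("the signed interaction term follows the log2FC sign", {
  preds <- make_pred_fixture("fA", "g1")
  ex <- expr_fixture("fA", "g1")
  feats <- build_pair_features(preds, ex$fe, ex$ge,
                               log2fc_sign = c(g1 = -1))
  expect_equal(feats$interaction_signed, -feats$interaction_unsigned)
  feats2 <- build_pair_features(preds, ex$fe, ex$ge)
  expect_equal(feats2$interaction_signed, feats2$interaction_unsigned)
})

test_that("the stratified split preserves class counts and is seeded", {
  pairs <- data.frame(label = rep(c(1, 0), c(20, 80)))
  sp <- split_train_test(pairs, 0.5, seed = 7)
  expect_equal(sum(sp$split == "train"), 50)
  expect_equal(sum(sp$split == "train" & sp$label == 1), 10)
  expect_identical(sp$split, split_train_test(pairs, 0.5, seed = 7)$split)
  expect_setequal(unique(sp$split), c("train", "test"))
  expect_error(split_train_test(data.frame(label = c(1, 0, 0)), 0.5, 1),
               "at least 2")
})

simulate_labeled_pairs <- function(n, shift, seed) {
  set.seed(seed)
  label <- rbinom(n, 1, 0.25)
  df <- data.frame(label = label)
  lam <- 0.3 + shift * sqrt(0.3) * label
  for (f in mirti:::FEATURE_NAMES) df[[f]] <- rnorm(n)
  df$total_context_score <- rnorm(n, -0.15, 0.12) - shift * 0.12 * label
  df$aggregate_pct <- rnorm(n, 0.3, 0.15) + shift * 0.15 * label
  for (f in c("n_cons_7m8", "n_cons_7a1", "n_cons_8mer")) df[[f]] <- rpois(n, lam)
  df$n_conserved_sites <- df$n_cons_7m8 + df$n_cons_7a1 + df$n_cons_8mer
  df
}

test_that("an infinite penalty gives the intercept-only null model exactly", {
  pairs <- simulate_labeled_pairs(400, 1, 91)
  fit <- fit_elastic_net(pairs, alpha = 0.5, lambda_grid = 1e9)
  expect_true(all(fit$coefficients_std == 0))
  prev <- mean(pairs$label)
  expect_equal(fit$intercept_std, qlogis(prev), tolerance = 1e-6)
  expect_equal(unique(round(predict(fit, pairs), 8)), round(prev, 8))
})

test_that("ridge fit matches a direct optimizer of the penalized deviance", {
  pairs <- simulate_labeled_pairs(150, 1, 92)
  lambda <- 0.07
  fit <- fit_elastic_net(pairs, alpha = 0, lambda_grid = lambda)
  X <- as.matrix(pairs[, mirti:::FEATURE_NAMES])
  Xs <- scale(X)
  y <- pairs$label
  n <- nrow(Xs)
  obj <- function(par) {
    eta <- par[1] + drop(Xs %*% par[-1])
    -mean(y * eta - log1p(exp(eta))) + lambda / 2 * sum(par[-1]^2)
  }
  opt <- optim(rep(0, ncol(Xs) + 1), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(fit$coefficients_std), opt$par[-1], tolerance = 1e-3)
  expect_equal(fit$intercept_std, opt$par[1], tolerance = 1e-3)
})

test_that("the classifier separates shifted features and is calibrated by AUC", {
  pairs <- simulate_labeled_pairs(1200, 3, 93)
  pairs <- split_train_test(pairs, 0.5, seed = 5)
  fit <- fit_elastic_net(pairs, alpha = 0.5, seed = 6)
  ev <- evaluate_model(fit, pairs)
  expect_gt(ev$auc_train, 0.95)
  expect_gt(ev$auc_test, 0.9)
})

test_that("model evaluation computes AUC and PPV from first principles", {
  model <- structure(list(coefficients = setNames(c(1, rep(0, 15)),
                                                  mirti:::FEATURE_NAMES),
                          intercept = 0, features = mirti:::FEATURE_NAMES),
                     class = "mirti_enet")
  df <- simulate_labeled_pairs(4, 0, 94)[, mirti:::FEATURE_NAMES]
  df$aggregate_pct <- c(2.2, 1.4, 0.4, -1.4)  # posteriors 0.9, 0.8, 0.6, 0.2
  df$label <- c(1, 1, 0, 0)
  df$split <- "test"
  ev <- evaluate_model(model, df, cutoffs = 0.5, working_cutoff = 0.5)
  expect_equal(ev$auc_test, 1)
  expect_equal(ev$ppv_curve$ppv, 2 / 3)
  expect_equal(ev$fdr_at_cutoff, 1 / 3)
  df$label <- c(0, 1, 1, 0)  # one inversion
  expect_lt(evaluate_model(model, df)$auc_test, 1)

  set.seed(95)
  rnd <- simulate_labeled_pairs(2000, 0, 96)
  rnd <- split_train_test(rnd, 0.5, seed = 7)
  fit <- fit_elastic_net(rnd, alpha = 0.5, lambda_grid = c(0.05))
  aucs <- evaluate_model(fit, rnd)
  expect_gt(aucs$auc_test, 0.44)
  expect_lt(aucs$auc_test, 0.56)
})

test_that("MP-PCLIP selection is the tagged union and monotone in the cutoff", {
  pairs <- simulate_labeled_pairs(60, 2, 97)
  pairs$family_id <- paste0("f", rep(1:6, each = 10))
  pairs$gene_id <- paste0("g", rep(1:10, 6))
  fit <- fit_elastic_net(split_train_test(pairs, 0.5, seed = 1),
                         alpha = 0.5, lambda_grid = 0.02)
  parclip <- pairs[pairs$label == 1, c("family_id", "gene_id")][1:4, ]
  mp <- select_mp_pclip(fit, pairs, parclip, cutoff = 0.5)
  cnt <- attr(mp, "counts")
  expect_equal(unname(cnt["n_predicted"]),
               unname(cnt["n_parclip_supported"] + cnt["n_additional"]))
  expect_equal(anyDuplicated(paste(mp$family_id, mp$gene_id)), 0)
  expect_true(all(mp$source %in% c("parclip", "model", "both")))
  expect_equal(sum(mp$source %in% c("parclip", "both")), nrow(parclip))

  high <- select_mp_pclip(fit, pairs, parclip, cutoff = 1.01)
  expect_equal(nrow(high), nrow(parclip))
  expect_true(all(high$source == "parclip"))

  prev <- Inf
  for (cc in c(0.2, 0.5, 0.8)) {
    sel <- attr(select_mp_pclip(fit, pairs, parclip, cutoff = cc), "counts")
    expect_lte(unname(sel["n_predicted"]), prev)
    prev <- unname(sel["n_predicted"])
  }
})

test_that("univariate associations recover label-coupled features", {
  pairs <- simulate_labeled_pairs(2000, 0, 98)
  pairs$aggregate_pct <- pairs$label  # identical to the label
  ua <- univariate_feature_assoc(pairs)
  expect_equal(nrow(ua), 16)
  expect_equal(ua$correlation[ua$feature == "aggregate_pct"], 1)
  noise <- ua$correlation[!ua$feature %in%
                            c("aggregate_pct", "total_context_score",
                              "n_cons_7m8", "n_cons_7a1", "n_cons_8mer",
                              "n_conserved_sites")]
  expect_true(all(abs(noise) < 0.07))
  pairs$mirna_variance <- 0
  ua2 <- univariate_feature_assoc(pairs)
  expect_true(is.na(ua2$correlation[ua2$feature == "mirna_variance"]))
})
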