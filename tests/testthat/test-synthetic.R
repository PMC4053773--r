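small_cfg <- function(...) {
  synth_config(n_genes = 40, n_families = 8,
               subtypes = c("luminal A" = 15, "basal-like" = 15),
               targets_per_family = 4, background_clusters = 8,
               decoy_clusters = 4, n_decoy_pairs = 120, ...)
}

test_that("the generator is fully deterministic given its config", {
  a <- synth_study(small_cfg(seed = 5))
  b <- synth_study(small_cfg(seed = 5))
  expect_identical(a$reference$transcripts, b$reference$transcripts)
  expect_identical(a$truth, b$truth)
  expect_identical(unclass(a$expression$mrna_expr),
                   unclass(b$expression$mrna_expr))
  expect_identical(a$reads, b$reads)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$annotation, b$annotation)
  c2 <- synth_study(small_cfg(seed = 6))
  expect_false(identical(a$reference$transcripts, c2$reference$transcripts))
})

test_that("the reference has distinct seeds and consistent region structure", {
  ref <- make_reference(small_cfg(seed = 7))
  expect_equal(anyDuplicated(ref$families$seed_2_8), 0)
  expect_true(all(nchar(ref$families$seed_2_8) == 7))
  expect_true(all(vapply(seq_len(nrow(ref$families)), function(i)
    substr(ref$families$mature_sequences[[i]][1], 2, 8) ==
      ref$families$seed_2_8[i], TRUE)))
  spans <- tapply(ref$model$end - ref$model$start, ref$model$transcript_id, sum)
  expect_true(all(spans == nchar(ref$transcripts[names(spans)])))
})

test_that("every planted interaction is representable in its 3'UTR", {
  cfg <- small_cfg(seed = 8)
  gt <- make_ground_truth(cfg, make_reference(cfg))
  utr3_start <- cfg$utr5_len + cfg$cds_len
  for (i in seq_len(nrow(gt$truth$target_map))) {
    row <- gt$truth$target_map[i, ]
    fam <- gt$reference$families
    site <- seed_site_sequences(fam$seed_2_8[fam$family_id == row$family_id])[["8mer"]]
    tx <- gt$reference$transcripts[[row$gene_id]]
    expect_identical(substr(tx, row$site_start + 1, row$site_start + 8), site)
    expect_gte(row$site_start, utr3_start)
    expect_identical(substr(tx, row$crosslink_pos + 1, row$crosslink_pos + 1), "T")
  }
})

test_that("miRNA counts normalize to RRF and repression tracks abundance", {
  cfg <- synth_config(n_genes = 60, n_families = 10,
                      subtypes = c("luminal A" = 80),
                      active_per_subtype = "all", beta = 1, sigma = 0.25,
                      seed = 9)
  ref <- make_reference(cfg)
  gt <- make_ground_truth(cfg, ref)
  ex <- simulate_expression_cohort(cfg, gt$truth, gt$reference)
  rrf <- compute_rrf(ex$mirna_counts)
  expect_true(all(abs(colSums(rrf) - 1) < 1e-9))
  fe <- family_expression(rrf, gt$reference$families)
  rec <- pair_correlations(fe, ex$mrna_expr,
                           gt$truth$target_map[, c("family_id", "gene_id")])
  sh <- correlation_shift(rec)
  expect_lt(sh$median_difference, 0)
  expect_lt(sh$wilcoxon_p, 0.01)

  # beta = 0 leaves targets indistinguishable from background
  cfg0 <- synth_config(n_genes = 60, n_families = 10,
                       subtypes = c("luminal A" = 80),
                       active_per_subtype = "all", beta = 0, seed = 10)
  gt0 <- make_ground_truth(cfg0, make_reference(cfg0))
  ex0 <- simulate_expression_cohort(cfg0, gt0$truth, gt0$reference)
  fe0 <- family_expression(compute_rrf(ex0$mirna_counts),
                           gt0$reference$families)
  sh0 <- correlation_shift(pair_correlations(
    fe0, ex0$mrna_expr, gt0$truth$target_map[, c("family_id", "gene_id")]))
  expect_gt(sh0$wilcoxon_p, 0.01)
})

test_that("the PAR-CLIP library recovers planted sites and filters decoys", {
  cfg <- small_cfg(seed = 11)
  study <- synth_study(cfg)
  clusters <- cluster_reads(study$reads)
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  # decoy read groups (2-4 reads) can never form a retained cluster
  read_groups <- unique(sub("_r[0-9]+$", "", study$reads$read_id))
  expect_true(any(grepl("^decoy", read_groups)))
  spans <- vapply(clusters, function(cl) cl$n_reads, 0)
  expect_true(all(spans >= 5))
  ccrs <- extract_ccrs(clusters, study$reference$transcripts)
  sites <- call_seed_sites(ccrs, study$reference$families)
  inter <- sites_to_interactions(sites, ccrs)
  planted <- unique(pair_key(study$truth$target_map$family_id,
                             study$truth$target_map$gene_id))
  found <- pair_key(inter$family_id, inter$gene_id)
  expect_true(all(planted %in% found))  # recall 1.0

  # zero crosslink probability leaves nothing above the 20% filter
  cfg0 <- small_cfg(seed = 12, crosslink_prob = 0)
  st0 <- synth_study(cfg0)
  expect_length(cluster_reads(st0$reads), 0)
})

test_that("prediction-table features separate true pairs only when shifted", {
  cfg <- small_cfg(seed = 13, feature_shift = 0)
  st <- synth_study(cfg)
  expect_true(all(st$predictions$n_conserved_sites ==
                    st$predictions$n_cons_7m8 + st$predictions$n_cons_7a1 +
                    st$predictions$n_cons_8mer))
  cnt_cols <- grep("^n_", names(st$predictions), value = TRUE)
  expect_true(all(st$predictions[cnt_cols] >= 0))
  expect_true(all(st$predictions[cnt_cols] == round(st$predictions[cnt_cols])))
  is_true <- attr(st$predictions, "is_true")
  d0 <- mean(st$predictions$total_context_score[is_true]) -
    mean(st$predictions$total_context_score[!is_true])
  expect_lt(abs(d0), 0.05)
  expect_error(simulate_prediction_table(small_cfg(feature_shift = -1),
                                         st$truth, st$reference),
               "feature_shift")
})

test_that("clinical simulation couples survival to the signature score", {
  cfg <- synth_config(n_genes = 60, n_families = 10,
                      subtypes = c("luminal A" = 200), hazard_ratio = 2,
                      seed = 14)
  ref <- make_reference(cfg)
  gt <- make_ground_truth(cfg, ref)
  ex <- simulate_expression_cohort(cfg, gt$truth, gt$reference)
  ann <- simulate_clinical(cfg, gt$truth, ex)
  expect_true(all(ann$overall_survival >= 0))
  expect_gt(sum(ann$survival_event), 10)
  expect_true(all(ann$tumor_size_class %in% c("<2", "2-5", ">5")))
  expect_true(all(ann$grade %in% c("good", "moderate", "poor")))
  sig <- intersect(gt$truth$signature_genes, rownames(ex$mrna_expr))
  z <- colMeans(unclass(ex$mrna_expr)[sig, ])
  fit <- survival::coxph(survival::Surv(ann$overall_survival,
                                        ann$survival_event) ~ scale(z))
  expect_lt(summary(fit)$coefficients[1, "Pr(>|z|)"], 0.01)
  expect_gt(exp(coef(fit)), 1.3)
  bad <- cfg; bad$hazard_ratio <- -1
  expect_error(simulate_clinical(bad, gt$truth, ex), "hazard_ratio")
})
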