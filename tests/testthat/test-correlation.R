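test_that("family expression aggregates member RRFs", {
  em <- make_em(rbind(c(0.01, 0.02), c(0.02, 0.03), c(0.97, 0.95)),
                scale = "rrf", entities = c("m1", "m2", "m3"))
  fam <- data.frame(family_id = c("fA", "fB"), seed_2_8 = c("AAAAAAA", "CCCCCCC"),
                    stringsAsFactors = FALSE)
  fam$member_ids <- list(c("m1", "m2"), "m3")
  fam$mature_sequences <- list(character(0), character(0))
  fe <- family_expression(em, fam)
  expect_equal(unname(unclass(fe)["fA", ]), c(0.03, 0.05))
  expect_equal(unname(unclass(fe)["fB", ]), c(0.97, 0.95))
  fam$member_ids <- list(c("m1", "m2"), "absent")
  expect_warning(fe2 <- family_expression(em, fam), "fB")
  expect_equal(nrow(fe2), 1)
})

test_that("pair correlations match the closed-form Pearson definition", {
  f <- make_em(matrix(c(1, 2, 3, 4, 5), 1, 5), scale = "a_value",
               entities = "fam1")
  g <- make_em(rbind(-c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), kind = "mrna",
               scale = "a_value", entities = c("gNeg", "gMix"))
  tm <- data.frame(family_id = "fam1", gene_id = "gNeg")
  rec <- pair_correlations(f, g, tm)
  expect_equal(rec$r[rec$gene_id == "gNeg"], -1)
  expect_true(rec$is_target[rec$gene_id == "gNeg"])
  expect_false(rec$is_target[rec$gene_id == "gMix"])
  # hand computation: r = cov(x,y) / (sd(x) sd(y))
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rec$r[rec$gene_id == "gMix"], r_hand)
  expect_equal(unique(rec$n_samples), 5)

  set.seed(71)
  n <- 1000
  fbig <- make_em(matrix(rnorm(n), 1, n), scale = "a_value", entities = "fam1")
  gbig <- make_em(matrix(rnorm(n), 1, n), kind = "mrna", scale = "a_value",
                  entities = "gI")
  expect_lt(abs(pair_correlations(fbig, gbig, tm)$r), 0.1)
  expect_error(pair_correlations(f[, 1:2], g[, 1:2], tm), "3 shared samples")
})

test_that("correlation shift reports signed median difference with Wilcoxon p", {
  rec <- data.frame(family_id = "f", gene_id = letters[1:5],
                    r = c(-0.5, -0.3, 0.0, 0.1, 0.2), n_samples = 10,
                    is_target = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  sh <- correlation_shift(rec)
  expect_equal(sh$median_difference, -0.5)  # medians -0.4 and 0.1
  expect_equal(sh$median_target_r, -0.4)
  expect_equal(sh$n_target_pairs, 2)

  same <- data.frame(family_id = "f", gene_id = letters[1:6],
                     r = rep(c(0.1, 0.2, 0.3), 2), n_samples = 10,
                     is_target = rep(c(TRUE, FALSE), each = 3))
  sh2 <- suppressWarnings(correlation_shift(same))
  expect_equal(sh2$median_difference, 0)
  expect_equal(sh2$wilcoxon_p, 1)
  expect_error(correlation_shift(rec[rec$is_target, ]), "non-empty")
})

test_that("exact Wilcoxon p agrees with exhaustive rank-sum enumeration", {
  tgt <- c(-0.62, -0.11, 0.25)
  bg <- c(-0.40, 0.05, 0.17, 0.33)
  rec <- data.frame(family_id = "f", gene_id = letters[1:7], r = c(tgt, bg),
                    n_samples = 10, is_target = rep(c(TRUE, FALSE), c(3, 4)))
  sh <- correlation_shift(rec)
  # enumerate all C(7,3) assignments of the pooled values to the target group
  pool <- c(tgt, bg)
  ranks <- rank(pool)
  combos <- utils::combn(7, 3)
  W_all <- apply(combos, 2, function(ix) sum(ranks[ix]) - 3 * 4 / 2)
  W_obs <- sum(ranks[1:3]) - 3 * 4 / 2
  p_lo <- mean(W_all <= W_obs); p_hi <- mean(W_all >= W_obs)
  p_exact <- min(1, 2 * min(p_lo, p_hi))
  expect_equal(sh$wilcoxon_p, p_exact)
})

test_that("threshold sweep covers the grid and respects filtering", {
  set.seed(72)
  f <- make_em(matrix(rlnorm(3 * 30, -2, 1), 3, 30), scale = "a_value",
               entities = c("f1", "f2", "f3"))
  g <- make_em(matrix(rnorm(10 * 30, 8), 10, 30), kind = "mrna",
               scale = "a_value")
  tm <- data.frame(family_id = c("f1", "f2"), gene_id = c("e1", "e2"))
  sw <- threshold_sweep(f, g, tm, mirna_grid = c(0, 1e-3, 1e-2),
                        mrna_grid = c(0, 6, 7, 9))
  expect_equal(nrow(sw), 12)
  base <- correlation_shift(pair_correlations(f, g, tm))
  expect_equal(sw$median_difference[sw$mirna_threshold == 0 &
                                      sw$mrna_threshold == 0],
               base$median_difference)
  # kept counts never increase as thresholds rise
  for (gt in unique(sw$mrna_threshold)) {
    sub <- sw[sw$mrna_threshold == gt, ]
    expect_true(all(diff(sub$n_mirnas[order(sub$mirna_threshold)]) <= 0))
  }
  expect_true(any(!sw$valid) || all(sw$valid))  # column exists and is logical
})

test_that("subtype shift isolates the subtype carrying the signal", {
  set.seed(73)
  n <- 40
  fam <- matrix(rlnorm(n, -2, 0.8), 1, 2 * n)
  rownames(fam) <- "f1"
  colnames(fam) <- sprintf("s%02d", 1:(2 * n))
  tgt <- rnorm(2 * n, 8, 0.3)
  tgt[1:n] <- tgt[1:n] - 2.5 * fam[1, 1:n] / mean(fam[1, 1:n])  # subtype A only
  bgm <- matrix(rnorm(6 * 2 * n, 8, 0.3), 6, 2 * n)
  g <- make_em(rbind(tgt, bgm), kind = "mrna", scale = "a_value",
               entities = paste0("g", 1:7), samples = colnames(fam))
  f <- structure(fam, class = c("ExpressionMatrix", "matrix", "array"),
                 entity_kind = "mirna", scale = "rrf")
  tm <- data.frame(family_id = "f1", gene_id = "g1")
  subtypes <- setNames(rep(c("basal-like", "luminal A"), each = n),
                       colnames(fam))
  sh <- subtype_shift(f, g, tm, subtypes)
  expect_equal(nrow(sh), 2)
  a <- sh$median_difference[sh$group_label == "basal-like"]
  b <- sh$median_difference[sh$group_label == "luminal A"]
  expect_lt(a, b)
  expect_lt(a, 0)
  # two subtypes holding copies of the same data give identical results
  fam2 <- cbind(fam[, 1:n, drop = FALSE], fam[, 1:n, drop = FALSE])
  g2m <- cbind(unclass(g)[, 1:n], unclass(g)[, 1:n])
  colnames(fam2) <- colnames(g2m) <- sprintf("d%02d", 1:(2 * n))
  f2 <- structure(fam2, class = c("ExpressionMatrix", "matrix", "array"),
                  entity_kind = "mirna", scale = "rrf")
  gg2 <- structure(g2m, class = c("ExpressionMatrix", "matrix", "array"),
                   entity_kind = "mrna", scale = "a_value")
  twin <- subtype_shift(f2, gg2, tm,
                        setNames(rep(c("HER2", "normal-like"), each = n),
                                 colnames(fam2)))
  expect_equal(twin$median_difference[1], twin$median_difference[2])
  expect_equal(twin$wilcoxon_p[1], twin$wilcoxon_p[2])
  expect_warning(subtype_shift(f, g, tm,
                               setNames(c("HER2", rep("luminal A", 2 * n - 1)),
                                        colnames(fam)),),
                 "skipping subtype HER2")
})

test_that("intronic host correlation strengthens with miRNA abundance", {
  set.seed(74)
  n <- 60; n_pairs <- 24
  abund <- exp(seq(log(1e-5), log(1e-2), length.out = n_pairs))
  mir <- matrix(0, n_pairs, n); host <- matrix(0, n_pairs, n)
  for (i in seq_len(n_pairs)) {
    latent <- rnorm(n)
    w <- (i - 1) / (n_pairs - 1)  # shared signal grows with abundance rank
    mir[i, ] <- abund[i] * exp(0.5 * (w * latent + (1 - w) * rnorm(n)))
    host[i, ] <- 8 + w * latent + (1 - w) * rnorm(n)
  }
  rownames(mir) <- paste0("mir", seq_len(n_pairs))
  rownames(host) <- paste0("hg", seq_len(n_pairs))
  colnames(mir) <- colnames(host) <- paste0("s", seq_len(n))
  me <- structure(mir, class = c("ExpressionMatrix", "matrix", "array"),
                  entity_kind = "mirna", scale = "rrf")
  he <- structure(host, class = c("ExpressionMatrix", "matrix", "array"),
                  entity_kind = "mrna", scale = "a_value")
  map <- setNames(rownames(host), rownames(mir))
  res <- intronic_host_analysis(me, he, map, n_bins = 4, B = 499, seed = 75)
  expect_equal(sum(res$bins$n), n_pairs)
  expect_true(all(diff(res$bins$mean_r) > 0))
  expect_lt(res$trend_p, 0.05)
  # a host identical to its miRNA correlates perfectly
  he2 <- structure(rbind(host, mir1copy = mir[1, ]),
                   class = c("ExpressionMatrix", "matrix", "array"),
                   entity_kind = "mrna", scale = "a_value")
  res2 <- intronic_host_analysis(me, he2, c(mir1 = "mir1copy"), n_bins = 1,
                                 B = 99, seed = 76)
  expect_equal(res2$pairs$r, 1)
  expect_error(intronic_host_analysis(me, he, c(zz = "none")), "no mapped")
})

test_that("rank concordance reproduces the average-rank Spearman formula", {
  a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  expect_equal(rank_concordance(a, a)$rho, 1)
  expect_equal(rank_concordance(a, setNames(rev(a), names(a)))$rho, -1)
  b <- c(g1 = 10, g2 = 30, g3 = 30, g4 = 50, g5 = 60, g6 = 70)
  a6 <- c(g1 = 3, g2 = 1, g3 = 4, g4 = 2, g5 = 6, g6 = 5)
  got <- rank_concordance(a6, b)
  ra <- rank(a6); rb <- rank(b)  # average ranks for the tie in b
  rho_hand <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(got$rho, rho_hand)
  expect_error(rank_concordance(a[1:2], a[1:2]), "3 shared")
})
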