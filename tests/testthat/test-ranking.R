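test_that("mean-rank aggregation handles extremes, ties and missing values", {
  ev <- rbind(best = c(0.001, 0.002, 0.003),
              mid1 = c(0.4, 0.6, 0.2),
              mid2 = c(0.6, 0.4, 0.7),
              worst = c(0.9, 0.95, 0.99))
  colnames(ev) <- c("a", "b", "c")
  rk <- rank_evidence(ev, B = 999, seed = 1)
  expect_equal(rk$family_id[1], "best")
  expect_equal(rk$combined_score[1], 1)
  # a perfect score is the extreme of the permutation null: its p sits at
  # the add-one floor plus the (small) chance of a tying permutation
  expect_gte(rk$rank_test_p[1], 1 / 1000)
  expect_lt(rk$rank_test_p[1], 0.05)
  expect_equal(rk$rank_test_p[1], min(rk$rank_test_p))

  tied <- matrix(0.5, 5, 3, dimnames = list(paste0("f", 1:5), NULL))
  rk2 <- rank_evidence(tied, B = 99, seed = 2)
  expect_true(all(rk2$combined_score == 3))  # (n + 1) / 2

  ev_na <- ev; ev_na["mid1", 2] <- NA
  rk3 <- rank_evidence(ev_na, B = 99, seed = 3)
  expect_equal(rk3$rank_b[rk3$family_id == "mid1"], 4)  # worst rank
  allna <- rbind(ev, gone = c(NA, NA, NA))
  expect_warning(rk4 <- rank_evidence(allna, B = 99, seed = 4), "gone")
  expect_false("gone" %in% rk4$family_id)
  expect_error(rank_evidence(ev[1, , drop = FALSE], B = 99), "2 families")
})

test_that("consistently relabeling families relabels the output", {
  set.seed(101)
  ev <- matrix(runif(30), 10, 3,
               dimnames = list(paste0("f", 1:10), c("a", "b", "c")))
  rk <- rank_evidence(ev, B = 199, seed = 5)
  relab <- ev
  rownames(relab) <- paste0("F", 10:1)  # same data, new names
  rk2 <- rank_evidence(relab, B = 199, seed = 5)
  map <- setNames(paste0("F", 10:1), paste0("f", 1:10))
  a <- setNames(rk$combined_score, rk$family_id)
  b <- setNames(rk2$combined_score, rk2$family_id)
  expect_equal(unname(a[paste0("f", 1:10)]),
               unname(b[map[paste0("f", 1:10)]]))
  pa <- setNames(rk$rank_test_p, rk$family_id)
  pb <- setNames(rk2$rank_test_p, rk2$family_id)
  expect_equal(unname(pa[paste0("f", 1:10)]),
               unname(pb[map[paste0("f", 1:10)]]))
})

make_activity_fixture <- function(seed, n = 50) {
  set.seed(seed)
  fams <- paste0("f", 1:6)
  genes <- paste0("g", 1:30)
  fe <- matrix(rlnorm(6 * n, -2, 0.6), 6, n,
               dimnames = list(fams, paste0("s", 1:n)))
  ge <- matrix(rnorm(30 * n, 8, 0.4), 30, n,
               dimnames = list(genes, paste0("s", 1:n)))
  # f1 and f2 are active: their targets track them negatively
  map <- data.frame(family_id = rep(fams, each = 3),
                    gene_id = genes[1:18], stringsAsFactors = FALSE)
  for (f in c("f1", "f2")) {
    tg <- map$gene_id[map$family_id == f]
    ge[tg, ] <- 8 - 2 * rep(fe[f, ] / mean(fe[f, ]), each = 3) +
      rnorm(3 * n, 0, 0.2)
  }
  fe <- structure(fe, class = c("ExpressionMatrix", "matrix", "array"),
                  entity_kind = "mirna", scale = "rrf")
  ge <- structure(ge, class = c("ExpressionMatrix", "matrix", "array"),
                  entity_kind = "mrna", scale = "a_value")
  sets <- lapply(split(map$gene_id, map$family_id), function(g)
    c(g, sample(genes[19:30], 4)))
  names(sets) <- paste0("path_", names(sets))
  list(fe = fe, ge = ge, map = map, sets = sets,
       cgc = c(map$gene_id[map$family_id %in% c("f1", "f2")], genes[25:30]))
}

test_that("activity ranking builds three evidence columns and finds active families", {
  fx <- make_activity_fixture(102)
  act <- activity_ranking(fx$fe, fx$ge, fx$map, fx$sets, fx$cgc,
                          B = 199, seed = 6)
  expect_equal(ncol(act$evidence), 3)
  expect_identical(colnames(act$evidence), c("target", "pathway", "cancer_genes"))
  expect_setequal(act$ranking$family_id[1:2], c("f1", "f2"))
  # family without any expressed target is excluded
  map2 <- fx$map[fx$map$family_id != "f3", ]
  act2 <- suppressMessages(activity_ranking(fx$fe, fx$ge, map2, fx$sets,
                                            fx$cgc, B = 99, seed = 7))
  expect_false("f3" %in% rownames(act2$evidence))
})

test_that("phenotype ranking tests each annotated clinical column", {
  fx <- make_activity_fixture(103)
  n <- ncol(fx$fe)
  score <- scale(colMeans(unclass(fx$ge)[fx$map$gene_id[fx$map$family_id == "f1"], ]))
  set.seed(104)
  ann <- data.frame(sample_id = colnames(fx$fe),
                    subtype = "luminal A",
                    lymph_node_positive = rbinom(n, 1, 0.4),
                    lymphovascular_invasion = rbinom(n, 1, 0.3),
                    tumor_size_class = sample(c("<2", "2-5", ">5"), n, TRUE),
                    grade = sample(c("good", "moderate", "poor"), n, TRUE),
                    time_to_metastasis = rexp(n, 0.1 * exp(0.8 * score)),
                    metastasis_event = 1L,
                    overall_survival = rexp(n, 0.1),
                    survival_event = rbinom(n, 1, 0.7),
                    stringsAsFactors = FALSE)
  ph <- phenotype_ranking(fx$fe, fx$ge, fx$map, ann, B = 199, seed = 8)
  expect_equal(ncol(ph$evidence), 6)
  expect_true(all(c("lymph_node", "grade", "survival") %in% colnames(ph$evidence)))
  # dropping a phenotype column narrows the evidence matrix
  ann2 <- ann[, setdiff(names(ann), c("grade"))]
  ph2 <- phenotype_ranking(fx$fe, fx$ge, fx$map, ann2, B = 99, seed = 9)
  expect_equal(ncol(ph2$evidence), 5)
})

test_that("survival signatures detect expression-driven hazard", {
  fx <- make_activity_fixture(105, n = 150)
  sig_genes <- fx$map$gene_id[fx$map$family_id == "f1"]
  z <- as.numeric(scale(colMeans(unclass(fx$ge)[sig_genes, ])))
  set.seed(106)
  t_event <- rexp(150, 0.1 * exp(log(2.5) * z))
  cens <- runif(150, 0, 25)
  time <- setNames(pmin(t_event, cens), colnames(fx$fe))
  event <- setNames(as.integer(t_event <= cens), colnames(fx$fe))
  sg <- survival_signature("f1", fx$fe, fx$ge, fx$map, time, event,
                           B = 499, seed = 10)
  expect_lt(sg$gt$p_perm, 0.01)
  expect_setequal(sg$genes, c("f1", sig_genes))
  expect_false(sg$adjusted)
  # adjusted mode absorbs a clinical driver
  clin <- data.frame(grade_num = z + rnorm(150, 0, 0.4))
  rownames(clin) <- colnames(fx$fe)
  sga <- survival_signature("f1", fx$fe, fx$ge, fx$map, time, event,
                            clinical = clin, B = 499, seed = 11)
  expect_true(sga$adjusted)
  expect_gt(sga$gt$p_perm, sg$gt$p_perm / 50)  # attenuated, not amplified
  expect_error(survival_signature("f1", fx$fe, fx$ge, fx$map, time,
                                  setNames(rep(0L, 150), names(event)),
                                  B = 99),
               "events")
})
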