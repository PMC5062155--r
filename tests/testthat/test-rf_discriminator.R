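test_that("subject-blocked splits partition subjects with no leakage", {
  subj <- setNames(paste0("P", 1:10), paste0("S", 1:10))  # 1 sample each
  plan <- make_subject_splits(subj, n_subsets = 25, train_fraction = 0.8,
                              seed = 2)
  for (s in plan$subsets) {
    expect_length(s$train, 8)        # exact divisibility: 8/2 every subset
    expect_length(s$validation, 2)
    expect_length(intersect(s$train, s$validation), 0)
    expect_setequal(c(s$train, s$validation), unique(subj))
  }
  # subsets distinct
  keys <- vapply(plan$subsets,
                 function(s) paste(sort(s$validation), collapse = "|"),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  # deterministic under seed
  plan2 <- make_subject_splits(subj, 25, 0.8, seed = 2)
  expect_identical(plan$subsets, plan2$subsets)
  expect_error(make_subject_splits(c(S1 = "P1", S2 = "P1"), 5, 0.8, 1),
               "single subject")
})

test_that("validation sizes concentrate near 20% with study-like subjects", {
  # 71 subjects, per-subject sample counts from the study's empirical
  # distribution; 300 subsets
  set.seed(10)
  n_per <- sample(1:8, 71, TRUE,
                  prob = c(14, 21, 19, 8, 9 / 4, 9 / 4, 9 / 4, 9 / 4) / 71)
  subj <- rep(sprintf("P%02d", 1:71), n_per)
  smap <- setNames(subj, sprintf("S%03d", seq_along(subj)))
  plan <- make_subject_splits(smap, 300, 0.8, seed = 1)
  nv <- vapply(plan$subsets, function(s) sum(smap %in% s$validation),
               numeric(1))
  n_total <- length(smap)
  expect_lt(abs(mean(nv) / n_total - 0.2), 0.02)
  expect_true(all(nv / n_total > 0.10 & nv / n_total < 0.30))
})

test_that("a perfectly separating feature dominates stage-1 importance", {
  fx <- separable_features()
  plan <- make_subject_splits(fx$subjects, 10, 0.8, seed = 3)
  panel <- stage1_select_panel(fx$features, fx$labels, plan, n_trees = 50,
                               panel_size = 3, seed = 3)
  expect_equal(names(panel$importance)[1], "F01")
  expect_equal(panel$panel[1], "F01")
  # deterministic under identical seeds
  panel2 <- stage1_select_panel(fx$features, fx$labels, plan, n_trees = 50,
                                panel_size = 3, seed = 3)
  expect_identical(panel$importance, panel2$importance)
  # permutation importance agrees on the dominant feature
  pperm <- stage1_select_panel(fx$features, fx$labels, plan, n_trees = 50,
                               panel_size = 3, seed = 3,
                               importance = "permutation")
  expect_equal(pperm$panel[1], "F01")
})

test_that("ties in mean importance break lexicographically by OTU id", {
  imp <- c(b = 1, a = 1, c = 2)
  ord <- order(-imp, names(imp), method = "radix")
  expect_equal(names(imp)[ord], c("c", "a", "b"))
})

test_that("stage-2 votes are conserved, bounded and reproducible", {
  fx <- separable_features(n_subjects = 14)
  plan <- make_subject_splits(fx$subjects, 40, 0.8, seed = 4)
  rep1 <- stage2_evaluate(fx$features, fx$labels, plan, n_trees = 50, seed = 4)
  v <- rep1$votes
  # each sample voted on exactly when its subject was in validation
  for (i in seq_len(nrow(v))) {
    subj_i <- fx$subjects[v$sample_id[i]]
    expected_models <- sum(vapply(plan$subsets,
                                  function(s) subj_i %in% s$validation,
                                  logical(1)))
    expect_equal(v$n_models[i], expected_models)
  }
  expect_true(all(v$vote_rate >= 0 & v$vote_rate <= 1, na.rm = TRUE))
  # vote conservation: active votes + remission votes = models voting
  expect_true(all(round(v$vote_rate * v$n_models) +
                  round((1 - v$vote_rate) * v$n_models) == v$n_models,
                  na.rm = TRUE))
  # perfectly separable features classify perfectly
  expect_equal(rep1$auc, 1.0)
  expect_equal(rep1$sensitivity, 1.0)
  expect_equal(rep1$specificity, 1.0)
  rep2 <- stage2_evaluate(fx$features, fx$labels, plan, n_trees = 50, seed = 4)
  expect_identical(rep1$votes, rep2$votes)
})

test_that("AUC by trapezoid equals the Mann-Whitney rank statistic", {
  set.seed(6)
  for (i in 1:20) {
    score <- round(runif(60), 2)  # rounding forces ties
    truth <- runif(60) < 0.5
    if (!any(truth) || all(truth)) next
    roc <- roc_curve(score, truth)
    expect_equal(auc_trapezoid(roc), auc_rank(score, truth),
                 tolerance = 1e-10)
  }
  # degenerate perfect case
  roc <- roc_curve(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc_trapezoid(roc), 1.0)
})

test_that("predictive values reproduce the published arithmetic", {
  m <- classification_metrics(sensitivity = 0.79, specificity = 0.73,
                              n_active = 97, n_remission = 88)
  expect_equal(round(m$ppv, 2), 0.76)
  expect_equal(round(m$npv, 2), 0.76)
})

test_that("proximities are proper similarities and separate classes", {
  fx <- separable_features(n_subjects = 10)
  plan <- make_subject_splits(fx$subjects, 12, 0.8, seed = 8)
  rep1 <- stage2_evaluate(fx$features, fx$labels, plan, n_trees = 40,
                          seed = 8, proximity = TRUE)
  prox <- rep1$proximity
  expect_equal(unname(diag(prox)), rep(1, nrow(prox)))
  expect_equal(prox, t(prox))
  expect_true(all(prox >= 0 & prox <= 1))
  same <- outer(fx$labels, fx$labels, "==")
  off <- !diag(nrow(prox))
  expect_gt(mean(prox[same & off]), mean(prox[!same]))
  # MDS embedding separates the two classes along some axis
  pca <- proximity_pca(prox)
  expect_equal(pca$sample_id, rownames(prox))
  d1 <- abs(mean(pca$PC1[fx$labels == "active"]) -
            mean(pca$PC1[fx$labels == "remission"]))
  expect_gt(d1, 0)
})

test_that("stage-1/stage-2 guardrails fire", {
  fx <- separable_features(n_subjects = 6)
  plan <- make_subject_splits(fx$subjects, 4, 0.8, seed = 1)
  expect_error(stage2_evaluate(fx$features[, 0, drop = FALSE], fx$labels,
                               plan, 10, 1), "non-empty")
  one_class <- setNames(rep("active", length(fx$labels)), names(fx$labels))
  expect_error(stage1_select_panel(fx$features, one_class, plan, 10, 2, 1),
               "single class")
})
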