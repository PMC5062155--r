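test_that("2x2 chi-square matches hand-derived closed forms", {
  # counts reconstructed from the baseline groups (35 active, 36 remission):
  # 37.1% of 35 = 13 vs 11.1% of 36 = 4
  fuso <- two_by_two_test(13, 22, 4, 32)
  expect_equal(fuso$statistic, 6.6038, tolerance = 1e-3)
  expect_equal(fuso$p, 0.0102, tolerance = 1e-2)
  # 17.1% of 35 = 6 vs 50.0% of 36 = 18
  verr <- two_by_two_test(6, 29, 18, 18)
  expect_equal(verr$statistic, 8.5621, tolerance = 1e-3)
  expect_equal(verr$p, 0.0034, tolerance = 1e-2)
  # identical proportions: no signal
  none <- two_by_two_test(10, 10, 10, 10)
  expect_equal(none$statistic, 0)
  expect_equal(none$p, 1)
})

test_that("2x2 test invariances and guards", {
  a <- two_by_two_test(13, 22, 4, 32)
  # swapping rows and columns simultaneously leaves the statistic unchanged
  b <- two_by_two_test(32, 4, 22, 13)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_error(two_by_two_test(0, 0, 5, 5), "margin")
  expect_error(two_by_two_test(1.5, 2, 3, 4), "integer")
  f <- two_by_two_test(13, 22, 4, 32, method = "fisher")
  expect_true(f$p > 0 && f$p <= 1)
  # the chi-square test agrees with base R's uncorrected version
  base_p <- stats::chisq.test(matrix(c(13, 4, 22, 32), 2), correct = FALSE)$p.value
  expect_equal(a$p, base_p, tolerance = 1e-12)
})

test_that("phylum prevalence counts presence per sample per group", {
  tbl <- tiny_table()
  labels <- c(S1 = "active", S2 = "active", S3 = "remission", S4 = "remission")
  out <- phylum_prevalence(tbl, labels)
  fuso <- out[out$taxon == "Fusobacteria", ]
  expect_equal(fuso$n_active_present, 1)   # only S1 has OTU2 > 0
  expect_equal(fuso$frac_remission, 0)
  firm <- out[out$taxon == "Firmicutes", ]  # OTU1 everywhere
  expect_equal(firm$frac_active, 1)
  expect_equal(firm$frac_remission, 1)
  # 31 of 97: the published rounding
  expect_equal(round(100 * 31 / 97, 1), 32.0)
  # unparseable taxonomy pools as unclassified
  tbl2 <- otu_table(tbl$counts, setNames(rep("junk", 5), colnames(tbl$counts)))
  out2 <- phylum_prevalence(tbl2, labels)
  expect_equal(out2$taxon, "unclassified")
})

test_that("Friedman screen: ties, planted effect, BH monotonicity", {
  set.seed(21)
  n_subj <- 12
  ids <- sprintf("S%02d", 1:(2 * n_subj))
  subj <- setNames(rep(sprintf("P%02d", 1:n_subj), each = 2), ids)
  lev <- setNames(rep(c("on", "off"), n_subj), ids)
  X <- matrix(rnorm(length(ids) * 6), length(ids),
              dimnames = list(ids, paste0("F", 1:6)))
  X[, 3] <- X[, 3] + ifelse(lev == "on", 3, 0)   # planted confounding
  scr <- friedman_screen(X, lev, subj)
  expect_equal(scr$table$feature[which.min(scr$table$q)], "F3")
  expect_true(scr$confounded)
  # q >= p elementwise; q non-decreasing along sorted p
  expect_true(all(scr$table$q >= scr$table$p - 1e-12))
  o <- order(scr$table$p)
  expect_true(all(diff(scr$table$q[o]) >= -1e-12))
  # all-identical observations: statistic 0, p 1
  Xc <- matrix(5, length(ids), 2, dimnames = list(ids, c("F1", "F2")))
  scr0 <- friedman_screen(Xc, lev, subj)
  expect_equal(scr0$table$statistic, c(0, 0))
  expect_equal(scr0$table$p, c(1, 1))
  expect_false(scr0$confounded)
  expect_error(friedman_screen(X, setNames(rep("on", length(ids)), ids), subj),
               ">= 2 levels")
})

test_that("Friedman screen under the null flags ~nothing at q < 0.05", {
  set.seed(31)
  n_subj <- 15
  ids <- sprintf("S%02d", 1:(2 * n_subj))
  subj <- setNames(rep(sprintf("P%02d", 1:n_subj), each = 2), ids)
  lev <- setNames(rep(c("on", "off"), n_subj), ids)
  hits <- 0
  for (r in 1:10) {
    X <- matrix(rnorm(length(ids) * 20), length(ids),
                dimnames = list(ids, paste0("F", 1:20)))
    hits <- hits + sum(friedman_screen(X, lev, subj)$table$q < 0.05)
  }
  expect_lte(hits / 200, 0.02)
})

test_that("panel-FC correlation: exact recovery, permutation p behavior", {
  set.seed(41)
  X <- matrix(rnorm(60 * 5), 60, dimnames = list(sprintf("S%02d", 1:60),
                                                 paste0("F", 1:5)))
  fc_lin <- drop(X %*% c(1, -2, 0.5, 0, 1)) + 3
  out <- panel_fc_correlation(X, setNames(fc_lin, rownames(X)),
                              n_permutations = 99, seed = 1)
  expect_equal(out$r, 1, tolerance = 1e-10)
  expect_lte(out$p, 1 / 50)  # smallest attainable region
  expect_error(panel_fc_correlation(X, rep(1, 60)), "constant")
  # overfitting inflation: many predictors on noise give large R, but p stays
  # unremarkable -- the permutation test carries the inference
  Xbig <- matrix(rnorm(60 * 40), 60, dimnames = list(rownames(X),
                                                     paste0("G", 1:40)))
  noise <- rnorm(60)
  out2 <- panel_fc_correlation(Xbig, setNames(noise, rownames(X)),
                               n_permutations = 199, seed = 2)
  expect_gt(out2$r, 0.5)
  expect_gt(out2$p, 0.05)
  expect_lte(out2$p, 1)
})
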