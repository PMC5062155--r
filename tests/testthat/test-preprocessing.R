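test_that("singleton removal drops total-count-1 OTUs only", {
  counts <- cbind(A = c(1, 0, 0), B = c(2, 0, 0), C = c(1, 1, 0), D = 0)
  rownames(counts) <- paste0("S", 1:3)
  tbl <- otu_table(counts)
  out <- remove_singletons(tbl)
  expect_setequal(colnames(out$counts), c("B", "C", "D"))  # total 2 retained
  empty <- otu_table(matrix(0, 2, 2, dimnames = list(c("S1", "S2"), c("A", "B")))[, 0, drop = FALSE])
  expect_equal(ncol(remove_singletons(empty)$counts), 0)
})

test_that("rarefaction draws exactly depth reads without replacement", {
  counts <- rbind(S1 = c(A = 4000, B = 930), S2 = c(A = 10, B = 0),
                  S3 = c(A = 3000, B = 1000))
  tbl <- otu_table(counts)
  out <- rarefy(tbl, depth = 4930, seed = 3)
  # S1 has exactly 4930 reads: subsample = whole sample
  expect_equal(out$counts["S1", ], c(A = 4000, B = 930))
  # S2 and S3 below depth: dropped and logged
  expect_setequal(attr(out, "dropped_samples"), c("S2", "S3"))
  expect_equal(rownames(out$counts), "S1")
  # forced outcome at tiny scale
  t2 <- otu_table(rbind(S1 = c(A = 10, B = 0)))
  expect_equal(rarefy(t2, 5, seed = 1)$counts["S1", ], c(A = 5, B = 0))
  expect_error(rarefy(t2, 0), "depth")
  # determinism + support preservation
  t3 <- otu_table(rbind(S1 = c(A = 6, B = 4, C = 0, D = 100)))
  expect_identical(rarefy(t3, 50, seed = 9)$counts, rarefy(t3, 50, seed = 9)$counts)
  expect_equal(unname(rarefy(t3, 50, seed = 9)$counts[1, "C"]), 0)
  expect_true(all(rowSums(rarefy(t3, 50, seed = 9)$counts) == 50))
})

test_that("rarefaction matches the hypergeometric expectation (oracle)", {
  # sample {A:6, B:4}, depth 5: E[A] = 5 * 6/10 = 3; compare both this
  # implementation and vegan's independent subsampler to the closed form
  t1 <- otu_table(rbind(S1 = c(A = 6, B = 4)))
  reps <- 4000
  mine <- vapply(seq_len(reps),
                 function(s) rarefy(t1, 5, seed = s)$counts[1, "A"],
                 numeric(1))
  # sd of the hypergeometric count is sqrt(5*.6*.4*5/9) ~ 0.816
  expect_lt(abs(mean(mine) - 3.0), 4 * 0.816 / sqrt(reps))
  skip_if_not_installed("vegan")
  set.seed(11)
  veg <- suppressWarnings(
    replicate(reps, vegan::rrarefy(c(A = 6, B = 4), 5)[1]))
  expect_lt(abs(mean(veg) - mean(mine)), 5 * 0.816 * sqrt(2 / reps))
})

test_that("prevalence filter applies the inclusive 20% rule per group", {
  n_a <- 97; n_r <- 97
  ids <- c(sprintf("A%02d", 1:n_a), sprintf("R%02d", 1:n_r))
  labels <- setNames(rep(c("active", "remission"), c(n_a, n_r)), ids)
  counts <- matrix(0, n_a + n_r, 3,
                   dimnames = list(ids, c("keep20", "drop19", "keepall")))
  counts[1:20, "keep20"] <- 1          # 20/97 = 0.206 >= 0.20 in active
  counts[c(1:19, 98:116), "drop19"] <- 1  # 19/97 = 0.196 in both groups
  counts[, "keepall"] <- 2
  tbl <- otu_table(counts)
  out <- prevalence_filter(tbl, labels)
  expect_setequal(colnames(out$counts), c("keep20", "keepall"))
  # idempotent
  expect_identical(prevalence_filter(out, labels)$counts, out$counts)
  expect_error(prevalence_filter(tbl, setNames(rep("active", n_a + n_r), ids)),
               "zero samples")
})

test_that("asinh transform has its closed form and monotonicity", {
  expect_identical(asinh(0), 0)
  fm <- asinh_transform(otu_table(rbind(S1 = c(A = 0, B = 1, C = 100))))
  expect_equal(fm[1, "B"], log(1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(fm[1, "A"], 0)
  set.seed(2)
  x <- sort(runif(50, 0, 1e4))
  expect_true(all(diff(asinh(x)) > 0))
  expect_true(attr(fm, "transformed"))
})

test_that("subject centering zeroes per-subject column means", {
  X <- rbind(S1 = c(F1 = 2, F2 = 5), S2 = c(F1 = 4, F2 = 1),
             S3 = c(F1 = 7, F2 = 7))
  fm <- otupanel:::feature_matrix(X, transformed = TRUE)
  subj <- c(S1 = "P1", S2 = "P1", S3 = "P2")
  out <- subject_center(fm, subj)
  expect_equal(unname(out["S1", "F1"]), -1)
  expect_equal(unname(out["S2", "F1"]), 1)
  expect_equal(unname(out["S3", ]), c(0, 0))  # single-sample subject
  expect_error(subject_center(fm, subj[1:2]), "unmapped")
  # property at realistic scale, tolerance 1e-12
  co <- test_cohort(seed = 2)
  f2 <- subject_center(asinh_transform(co$table), cohort_subjects(co))
  for (s in unique(cohort_subjects(co))) {
    rows <- names(which(cohort_subjects(co) == s))
    expect_lt(max(abs(colMeans(f2[rows, , drop = FALSE]))), 1e-12)
  }
  expect_true(attr(f2, "centered"))
})
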