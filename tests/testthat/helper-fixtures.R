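# Fixtures are generated in code. Cohorts at the reduced test scale are
# cached per (seed, effect_size) within a test run because several files
# reuse them.

.cohort_cache <- new.env(parent = emptyenv())

test_spec <- function(seed = 1, effect_size = 6, n_subjects = 40,
                      n_otus = 500, n_discriminatory = 20) {
  cohort_spec(n_subjects = n_subjects,
              samples_per_subject_range = c(2, 4),
              n_otus = n_otus, n_discriminatory = n_discriminatory,
              effect_size = effect_size,
              depth_mean = 6000, depth_sd = 400, seed = seed)
}

test_cohort <- function(seed = 1, effect_size = 6, ...) {
  key <- paste(seed, effect_size, ...)
  if (!exists(key, envir = .cohort_cache))
    assign(key, generate_cohort(test_spec(seed, effect_size, ...)),
           envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

cohort_labels <- function(cohort) {
  setNames(cohort$metadata$state, cohort$metadata$sample_id)
}

cohort_subjects <- function(cohort) {
  setNames(cohort$metadata$subject_id, cohort$metadata$sample_id)
}

# A tiny handmade table: 4 samples x 5 OTUs with known totals.
tiny_table <- function() {
  counts <- rbind(
    S1 = c(10, 1, 0, 3, 2),
    S2 = c( 5, 0, 0, 4, 0),
    S3 = c( 8, 0, 1, 2, 1),
    S4 = c( 2, 0, 0, 6, 0))
  colnames(counts) <- paste0("OTU", 1:5)
  otu_table(counts, setNames(
    sprintf("k__Bacteria; p__%s; c__; o__; f__; g__; s__",
            c("Firmicutes", "Fusobacteria", "Verrucomicrobia",
              "Bacteroidetes", "Firmicutes")),
    colnames(counts)))
}

# Features with one perfectly separating column, n subjects x 2 samples.
separable_features <- function(n_subjects = 12, n_features = 8, seed = 5) {
  withr::with_seed(seed, {
    n <- n_subjects * 2
    ids <- sprintf("S%02d", seq_len(n))
    subj <- setNames(rep(sprintf("P%02d", seq_len(n_subjects)), each = 2), ids)
    lab <- setNames(rep(c("active", "remission"), length.out = n), ids)
    X <- matrix(rnorm(n * n_features), n,
                dimnames = list(ids, sprintf("F%02d", seq_len(n_features))))
    X[, 1] <- ifelse(lab == "active", 1, -1) + rnorm(n, 0, 0.01)
    list(features = otupanel:::feature_matrix(X, TRUE, TRUE),
         labels = lab, subjects = subj)
  })
}
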