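#' Pipeline configuration
#'
#' All defaults are the reference analysis constants: rarefaction to 4930
#' reads, 20\% group prevalence, 90 panel-selection subsets and 300
#' classification subsets of 700 trees each, a 50-OTU panel, 80/20
#' subject-blocked splits, majority vote at 0.5, FDR 0.05.
#'
#' @param rarefaction_depth,prevalence_threshold,stage1_subsets,stage2_subsets
#'   see description.
#' @param n_trees,panel_size,train_fraction,vote_threshold,fdr_alpha idem.
#' @param cca_permutations permutations for the panel-FC correlation test.
#' @param proximity_models stage-2 models used for the proximity matrix.
#' @param seed master seed; per-stage seeds fan out deterministically.
#' @return validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(rarefaction_depth = 4930,
                            prevalence_threshold = 0.20,
                            stage1_subsets = 90, stage2_subsets = 300,
                            n_trees = 700, panel_size = 50,
                            train_fraction = 0.8, vote_threshold = 0.5,
                            fdr_alpha = 0.05, cca_permutations = 999,
                            proximity_models = 30, seed = 1) {
  cfg <- as.list(environment())
  if (rarefaction_depth < 1 || n_trees < 1 || panel_size < 1 ||
      stage1_subsets < 1 || stage2_subsets < 1)
    stop("all counts must be positive")
  if (prevalence_threshold <= 0 || prevalence_threshold > 1)
    stop("prevalence_threshold must be in (0, 1]")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path JSON file to write to / read from.
#' @param config a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

# 32-bit FNV-1a over the config's JSON serialization; carried in output
# headers for provenance (no cryptographic intent).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keeps h a non-negative double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run the whole analysis
#'
#' Orchestrates labeling and exclusions, preprocessing, alpha diversity,
#' the two random-forest stages, and the supporting statistics, writing all
#' artifacts to \code{out_dir}: \code{labels.tsv}, \code{diversity.tsv},
#' \code{panel.tsv}, \code{votes.tsv}, \code{roc.csv}, \code{pca.tsv},
#' \code{metrics.json} and a run log listing every excluded sample with its
#' reason and all derived seeds.
#'
#' @param config \code{\link{pipeline_config}}.
#' @param table an \code{\link{otu_table}} (or \code{table_path} to read).
#' @param meta metadata data.frame (or \code{meta_path}).
#' @param table_path,meta_path optional file inputs.
#' @param out_dir output directory (created); NULL skips file output.
#' @return invisible list with all intermediate objects and the metrics.
#' @export
run_pipeline <- function(config, table = NULL, meta = NULL,
                         table_path = NULL, meta_path = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(table)) table <- read_otu_table(table_path)
  if (is.null(meta)) meta <- read_metadata(meta_path)
  log_lines <- c(sprintf("config_hash: %s", config_hash(config)),
                 sprintf("seed: %d", config$seed))

  labels_df <- apply_exclusions(meta)
  for (bad in c("excluded", "indeterminate")) {
    ids <- labels_df$sample_id[labels_df$label == bad]
    for (id in ids) log_lines <- c(log_lines, sprintf("drop %s: %s", id, bad))
  }
  labels <- modeling_labels(labels_df)
  subject_map <- setNames(meta$subject_id, meta$sample_id)

  for (g in c("active", "remission"))
    if (length(unique(subject_map[names(labels)[labels == g]])) < 2)
      stop("fewer than 2 subjects with ", g,
           " samples after exclusions; aborting")

  seed_rarefy <- derive_seed(config$seed, "rarefy")
  prep <- preprocess(table, labels, subject_map,
                     depth = config$rarefaction_depth,
                     threshold = config$prevalence_threshold,
                     seed = seed_rarefy)
  for (id in prep$dropped)
    log_lines <- c(log_lines, sprintf("drop %s: below rarefaction depth", id))
  labels <- labels[rownames(prep$features)]
  subject_map_kept <- subject_map[names(labels)]

  div <- group_diversity_summary(prep$rarefied, labels)

  s1_seed <- derive_seed(config$seed, "splits_stage1")
  plan1 <- make_subject_splits(subject_map_kept, config$stage1_subsets,
                               config$train_fraction, seed = s1_seed)
  panel <- stage1_select_panel(prep$features, labels, plan1,
                               n_trees = config$n_trees,
                               panel_size = config$panel_size,
                               seed = derive_seed(config$seed, "stage1"))

  s2_seed <- derive_seed(config$seed, "splits_stage2")
  plan2 <- make_subject_splits(subject_map_kept, config$stage2_subsets,
                               config$train_fraction, seed = s2_seed)
  report <- stage2_evaluate(prep$features[, panel$panel, drop = FALSE],
                            labels, plan2, n_trees = config$n_trees,
                            seed = derive_seed(config$seed, "stage2"),
                            vote_threshold = config$vote_threshold,
                            proximity = TRUE,
                            proximity_models = config$proximity_models)
  pca <- proximity_pca(report$proximity)

  phyla <- phylum_prevalence(prep$rarefied, labels)
  cca <- panel_fc_correlation(
    prep$features[, panel$panel, drop = FALSE],
    setNames(meta$fc, meta$sample_id)[names(labels)],
    n_permutations = config$cca_permutations,
    seed = derive_seed(config$seed, "cca"))

  metrics <- list(auc = report$auc, sensitivity = report$sensitivity,
                  specificity = report$specificity, ppv = report$ppv,
                  npv = report$npv, panel_size = length(panel$panel),
                  n_samples = length(labels),
                  n_active = sum(labels == "active"),
                  n_remission = sum(labels == "remission"),
                  cca_r = cca$r, cca_p = cca$p,
                  config_hash = config_hash(config))
  log_lines <- c(log_lines,
                 sprintf("seeds: rarefy=%d splits1=%d stage1=%d splits2=%d stage2=%d cca=%d",
                         seed_rarefy, s1_seed,
                         derive_seed(config$seed, "stage1"), s2_seed,
                         derive_seed(config$seed, "stage2"),
                         derive_seed(config$seed, "cca")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(labels_df, file.path(out_dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(otu_id = names(panel$importance),
                           importance = unname(panel$importance),
                           in_panel = names(panel$importance) %in% panel$panel),
                file.path(out_dir, "panel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(report$votes, file.path(out_dir, "votes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.csv(report$roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
    write.table(pca, file.path(out_dir, "pca.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  invisible(list(labels = labels_df, preprocessed = prep, diversity = div,
                 panel = panel, report = report, pca = pca, phyla = phyla,
                 cca = cca, metrics = metrics, log = log_lines))
}
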