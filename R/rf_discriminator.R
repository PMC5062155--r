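#' Build subject-blocked train/validation split plans
#'
#' Every subset keeps all samples of a subject on one side, so a model is
#' never trained on part of a patient's samples and validated on the rest.
#' Per subset, subjects are shuffled and greedily assigned to the training
#' side until the cumulative sample count first reaches
#' \code{train_fraction} of all samples; the remaining subjects validate.
#' Subsets are distinct across the plan (re-drawn on collision).
#'
#' @param subject_map named character vector, sample id -> subject id.
#' @param n_subsets number of subject partitions to draw (90 for panel
#'   selection, 300 for classification in the reference design).
#' @param train_fraction target fraction of samples on the training side
#'   (default 0.8).
#' @param seed RNG seed.
#' @return an object of class \code{split_plan}: list of subsets, each a
#'   list(train, validation) of subject ids.
#' @export
make_subject_splits <- function(subject_map, n_subsets, train_fraction = 0.8,
                                seed = NULL) {
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_per_subject <- table(subject_map)
  subjects <- names(n_per_subject)
  if (length(subjects) < 2) stop("cannot split a single subject")
  target <- train_fraction * sum(n_per_subject)
  with_seed(seed, {
    subsets <- vector("list", n_subsets)
    seen <- character(0)
    attempts <- 0
    i <- 1
    while (i <= n_subsets) {
      attempts <- attempts + 1
      if (attempts > 1000 * n_subsets)
        stop("cannot produce ", n_subsets, " distinct subject subsets")
      ord <- sample(subjects)
      cum <- cumsum(n_per_subject[ord])
      n_train <- which(cum >= target)[1]
      if (n_train >= length(subjects)) n_train <- length(subjects) - 1
      key <- paste(sort(ord[seq_len(n_train)]), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      subsets[[i]] <- list(train = ord[seq_len(n_train)],
                           validation = ord[-seq_len(n_train)])
      i <- i + 1
    }
    structure(list(subsets = subsets, train_fraction = train_fraction,
                   seed = seed, subject_map = subject_map),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  nv <- vapply(x$subsets, function(s) {
    sum(x$subject_map %in% s$validation)
  }, numeric(1))
  cat(sprintf("split_plan: %d subject-blocked subsets, %d subjects, validation %d-%d samples\n",
              length(x$subsets), length(unique(x$subject_map)),
              min(nv), max(nv)))
  invisible(x)
}

# Assert the no-leakage contract: each subset's sides are disjoint subject
# sets that together cover all subjects. Called defensively before fitting.
validate_split_plan <- function(plan, subject_map = plan$subject_map) {
  subjects <- unique(subject_map)
  for (s in plan$subsets) {
    if (length(intersect(s$train, s$validation)) > 0)
      stop("subject leakage: a subject appears on both sides of a subset")
    if (!setequal(c(s$train, s$validation), subjects))
      stop("subset does not partition the subject set")
  }
  invisible(TRUE)
}

rf_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

# Fit one forest; y_active is logical. min_node = 1 and mtry = sqrt(p) are
# the conventional classification defaults.
fit_forest <- function(X, y_active, n_trees, seed, mtry = NULL) {
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  .cpp_rf_fit(X, as.integer(y_active), as.integer(n_trees),
              as.integer(mtry), 1L, as.integer(seed))
}

samples_of <- function(subject_map, subjects) {
  names(subject_map)[subject_map %in% subjects]
}

#' Stage 1: select the discriminatory OTU panel
#'
#' Fits one random forest per subject-blocked subset on the training side
#' only, averages each OTU's variable importance (mean decrease in Gini
#' impurity) across the subsets, and returns the top-ranked panel. Ties in
#' mean importance break by lexicographic OTU id.
#'
#' @param features preprocessed \code{feature_matrix}
#'   (asinh-transformed, subject-centered), samples x OTUs.
#' @param labels named "active"/"remission" vector covering all samples.
#' @param plan \code{split_plan} (90 subsets in the reference design).
#' @param n_trees trees per forest (default 700).
#' @param panel_size panel size (default 50).
#' @param seed integer seed; forest seeds fan out deterministically per subset.
#' @param importance "gini" (default) or "permutation" (hold-out accuracy
#'   drop on each subset's validation samples when one feature is permuted).
#' @return \code{panel_result}: list(importance = named mean scores, sorted
#'   decreasing; panel = ordered OTU ids; n_subsets_used; n_trees).
#' @export
stage1_select_panel <- function(features, labels, plan, n_trees = 700,
                                panel_size = 50, seed = 1,
                                importance = c("gini", "permutation")) {
  importance <- match.arg(importance)
  validate_split_plan(plan)
  X <- unclass(features)
  subject_map <- plan$subject_map
  imp_sum <- setNames(numeric(ncol(X)), colnames(X))
  with_seed(seed, {
    for (i in seq_along(plan$subsets)) {
      sub <- plan$subsets[[i]]
      tr <- samples_of(subject_map, sub$train)
      ytr <- labels[tr] == "active"
      if (length(unique(ytr)) < 2)
        stop("training side of subset ", i, " contains a single class")
      forest <- fit_forest(X[tr, , drop = FALSE], ytr, n_trees, rf_seed(seed, i))
      if (importance == "gini") {
        imp_sum <- imp_sum + forest$importance
      } else {
        va <- samples_of(subject_map, sub$validation)
        Xva <- X[va, , drop = FALSE]
        yva <- labels[va] == "active"
        base_acc <- mean((.cpp_rf_votes(forest, Xva) > 0.5) == yva)
        for (j in seq_len(ncol(X))) {
          Xp <- Xva
          Xp[, j] <- Xp[sample(nrow(Xp)), j]
          imp_sum[j] <- imp_sum[j] +
            base_acc - mean((.cpp_rf_votes(forest, Xp) > 0.5) == yva)
        }
      }
    }
  })
  imp <- imp_sum / length(plan$subsets)
  # decreasing importance, ties by OTU id
  ord <- order(-imp, names(imp), method = "radix")
  imp <- imp[ord]
  structure(list(importance = imp,
                 panel = names(imp)[seq_len(min(panel_size, length(imp)))],
                 n_subsets_used = length(plan$subsets), n_trees = n_trees),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("panel_result: %d OTUs selected from %d (averaged over %d subsets, %d trees)\n",
              length(x$panel), length(x$importance), x$n_subsets_used, x$n_trees))
  invisible(x)
}

#' Stage 2: majority-vote classification and performance report
#'
#' Fits one forest per subject-blocked subset on the panel features of the
#' training side and lets it classify that subset's validation samples. A
#' sample's vote rate is the fraction of models classifying it active among
#' the models in which it sat in validation; its hard label follows the
#' majority (> 0.5 active, < 0.5 remission, exactly 0.5 reported
#' indeterminate). The ROC sweeps a threshold over the pooled vote rates;
#' AUC is computed both by the trapezoidal rule and as the Mann-Whitney rank
#' statistic (the two agree to numerical precision).
#'
#' @param features \code{feature_matrix} restricted to the selected panel.
#' @param labels named "active"/"remission" truth covering all samples.
#' @param plan \code{split_plan} (300 subsets in the reference design).
#' @param n_trees trees per forest (default 700).
#' @param seed integer seed.
#' @param vote_threshold majority threshold (default 0.5).
#' @param proximity also accumulate random-forest proximities (fraction of
#'   trees in which two samples share a terminal node, averaged over models)
#'   for \code{\link{proximity_pca}}.
#' @param proximity_models number of subsets to use for proximities
#'   (default: all; fewer is cheaper and nearly identical).
#' @return \code{prediction_report}: votes table, roc, auc (trapezoid),
#'   auc_rank, sensitivity, specificity, ppv, npv, never_validated,
#'   optional proximity matrix.
#' @export
stage2_evaluate <- function(features, labels, plan, n_trees = 700, seed = 1,
                            vote_threshold = 0.5, proximity = FALSE,
                            proximity_models = NULL) {
  if (ncol(features) == 0) stop("panel must be non-empty")
  validate_split_plan(plan)
  X <- unclass(features)
  subject_map <- plan$subject_map
  ids <- rownames(X)
  votes_active <- setNames(numeric(length(ids)), ids)
  n_models <- setNames(integer(length(ids)), ids)
  prox_acc <- NULL
  n_prox_models <- 0L
  n_prox_trees <- 0L
  if (proximity) {
    prox_acc <- matrix(0, nrow(X), nrow(X), dimnames = list(ids, ids))
    proximity_models <- proximity_models %||% length(plan$subsets)
  }
  for (i in seq_along(plan$subsets)) {
    sub <- plan$subsets[[i]]
    tr <- samples_of(subject_map, sub$train)
    va <- samples_of(subject_map, sub$validation)
    ytr <- labels[tr] == "active"
    if (length(unique(ytr)) < 2)
      stop("training side of subset ", i, " contains a single class")
    forest <- fit_forest(X[tr, , drop = FALSE], ytr, n_trees,
                         rf_seed(seed, 100000 + i))
    if (length(va) > 0) {
      frac <- .cpp_rf_votes(forest, X[va, , drop = FALSE])
      votes_active[va] <- votes_active[va] + (frac > 0.5)
      n_models[va] <- n_models[va] + 1L
    }
    if (proximity && i <= proximity_models) {
      .cpp_prox_accumulate(.cpp_rf_leaves(forest, X), prox_acc)
      n_prox_models <- n_prox_models + 1L
      n_prox_trees <- n_prox_trees + n_trees
    }
  }
  never <- ids[n_models == 0]
  if (length(never) > 0)
    warning(length(never), " sample(s) never appeared in any validation set")
  vote_rate <- ifelse(n_models > 0, votes_active / n_models, NA_real_)
  hard <- ifelse(is.na(vote_rate), NA_character_,
                 ifelse(vote_rate > vote_threshold, "active",
                        ifelse(vote_rate < vote_threshold, "remission",
                               "indeterminate")))
  votes <- data.frame(sample_id = ids, vote_rate = vote_rate,
                      n_models = as.integer(n_models), hard_label = hard,
                      truth = unname(labels[ids]), stringsAsFactors = FALSE)
  scored <- votes[!is.na(votes$vote_rate), ]
  roc <- roc_curve(scored$vote_rate, scored$truth == "active")
  cm <- table(factor(scored$hard_label, c("active", "remission")),
              factor(scored$truth, c("active", "remission")))
  tp <- cm["active", "active"]; fn <- cm["remission", "active"]
  tn <- cm["remission", "remission"]; fp <- cm["active", "remission"]
  structure(list(
    votes = votes, roc = roc,
    auc = auc_trapezoid(roc), auc_rank = auc_rank(scored$vote_rate,
                                                  scored$truth == "active"),
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    never_validated = never,
    proximity = if (proximity && n_prox_models > 0)
      prox_acc / (n_prox_models * n_trees) else NULL,
    n_subsets = length(plan$subsets), n_trees = n_trees
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: %d samples, %d subsets x %d trees\n",
              nrow(x$votes), x$n_subsets, x$n_trees))
  cat(sprintf("  AUC %.3f | sens %.2f spec %.2f | PPV %.2f NPV %.2f\n",
              x$auc, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' ROC curve from scores
#'
#' @param score numeric vote rates (higher = more active-like).
#' @param is_positive logical truth (TRUE = active).
#' @return data.frame(threshold, fpr, tpr), from (1,1) down to (0,0) as the
#'   threshold rises through every distinct score.
#' @export
roc_curve <- function(score, is_positive) {
  stopifnot(length(score) == length(is_positive))
  thr <- c(-Inf, sort(unique(score)))
  pos <- sum(is_positive); neg <- sum(!is_positive)
  if (pos == 0 || neg == 0) stop("ROC needs both classes")
  tpr <- vapply(thr, function(t) sum(score > t & is_positive) / pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(score > t & !is_positive) / neg, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' @rdname roc_curve
#' @param roc a data.frame from \code{roc_curve}.
#' @export
auc_trapezoid <- function(roc) {
  ord <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[ord]; y <- roc$tpr[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @rdname roc_curve
#' @param is_positive logical truth vector.
#' @export
auc_rank <- function(score, is_positive) {
  r <- rank(score)
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Predictive values from sensitivity, specificity and class composition
#'
#' The standard confusion-matrix arithmetic: with \eqn{P} actual positives
#' and \eqn{N} actual negatives, \eqn{PPV = sens \cdot P / (sens \cdot P +
#' (1 - spec) \cdot N)} and \eqn{NPV = spec \cdot N / (spec \cdot N +
#' (1 - sens) \cdot P)}.
#'
#' @param sensitivity,specificity rates in [0, 1].
#' @param n_active,n_remission class sizes among evaluated samples.
#' @return list(ppv, npv).
#' @export
classification_metrics <- function(sensitivity, specificity, n_active,
                                   n_remission) {
  tp <- sensitivity * n_active
  fn <- (1 - sensitivity) * n_active
  tn <- specificity * n_remission
  fp <- (1 - specificity) * n_remission
  list(ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Proximity PCA (classical MDS on 1 - proximity)
#'
#' Converts the averaged random-forest proximity matrix to dissimilarities
#' \eqn{d = 1 - prox} and embeds the samples by classical multidimensional
#' scaling (PCA of the double-centered squared-dissimilarity matrix).
#'
#' @param prox symmetric proximity matrix in [0, 1], unit diagonal (from
#'   \code{\link{stage2_evaluate}} with \code{proximity = TRUE}).
#' @param k number of coordinates (default 2).
#' @return data.frame(sample_id, PC1, PC2, ...).
#' @export
proximity_pca <- function(prox, k = 2) {
  if (any(is.na(prox))) stop("proximity undefined for some sample pair")
  if (max(abs(prox - t(prox))) > 1e-8) stop("proximity must be symmetric")
  d <- 1 - prox
  diag(d) <- 0
  coords <- cmdscale(d, k = k)
  out <- data.frame(sample_id = rownames(prox), coords,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out) <- c("sample_id", paste0("PC", seq_len(k)))
  out
}
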