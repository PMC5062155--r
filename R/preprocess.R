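#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples equals exactly 1.
#'
#' @param table an \code{\link{otu_table}}.
#' @return the table without singleton OTUs.
#' @export
remove_singletons <- function(table) {
  keep <- colSums(table$counts) != 1
  subset_otus(table, otu_ids(table)[keep])
}

#' Rarefy samples to a common depth
#'
#' For each sample with at least \code{depth} reads, draws exactly
#' \code{depth} reads without replacement (multivariate hypergeometric).
#' Samples with fewer reads are dropped and recorded in the
#' \code{"dropped_samples"} attribute. Deterministic under a fixed seed.
#'
#' @param table an \code{otu_table}.
#' @param depth target depth, >= 1 (default 4930).
#' @param seed RNG seed.
#' @return rarefied \code{otu_table}; every row sums to exactly \code{depth}.
#' @export
rarefy <- function(table, depth = 4930, seed = NULL) {
  if (depth < 1) stop("depth must be >= 1")
  totals <- rowSums(table$counts)
  dropped <- sample_ids(table)[totals < depth]
  kept <- sample_ids(table)[totals >= depth]
  with_seed(seed, {
    out <- table$counts[kept, , drop = FALSE]
    for (s in kept) {
      row <- table$counts[s, ]
      tot <- sum(row)
      if (tot == depth) next
      # index the pooled reads: read k belongs to the OTU whose cumulative
      # count interval contains k
      picks <- sample.int(tot, depth)
      cum <- cumsum(row)
      otu_of_pick <- findInterval(picks - 1, c(0, cum), rightmost.closed = FALSE)
      out[s, ] <- tabulate(otu_of_pick, nbins = length(row))
    }
    res <- otu_table(out, table$taxonomy)
    attr(res, "dropped_samples") <- dropped
    res
  })
}

#' Filter OTUs by within-group prevalence
#'
#' Retains an OTU iff it is detected (count > 0) in at least
#' \code{threshold} (default 20\%) of the samples of at least one group.
#' The comparison is inclusive (>=). Idempotent.
#'
#' @param table an \code{otu_table} whose samples are all labeled.
#' @param labels named character vector (sample id -> "active"/"remission")
#'   covering every sample in the table.
#' @param threshold prevalence fraction in (0, 1].
#' @return filtered \code{otu_table}.
#' @export
prevalence_filter <- function(table, labels, threshold = 0.20) {
  ids <- sample_ids(table)
  if (!all(ids %in% names(labels)))
    stop("every sample must be labeled active or remission")
  grp <- labels[ids]
  if (!all(grp %in% c("active", "remission")))
    stop("labels must be 'active' or 'remission'")
  for (g in c("active", "remission"))
    if (sum(grp == g) == 0) stop("group with zero samples: ", g)
  present <- table$counts > 0
  frac_a <- colMeans(present[grp == "active", , drop = FALSE])
  frac_r <- colMeans(present[grp == "remission", , drop = FALSE])
  keep <- frac_a >= threshold | frac_r >= threshold
  subset_otus(table, otu_ids(table)[keep])
}

#' Inverse-hyperbolic-sine transform
#'
#' Elementwise \eqn{y = \log(x + \sqrt{x^2 + 1})}: defined at zero (0 -> 0),
#' strictly monotone, and approximately logarithmic for large counts, which
#' stabilises the skewed, sparse count distributions of OTU tables.
#'
#' @param table an \code{otu_table} (or bare numeric matrix).
#' @return a \code{feature_matrix}: numeric samples x OTUs matrix carrying
#'   \code{transformed}/\code{centered} provenance flags.
#' @export
asinh_transform <- function(table) {
  m <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  feature_matrix(asinh(m), transformed = TRUE, centered = FALSE)
}

feature_matrix <- function(values, transformed = FALSE, centered = FALSE) {
  structure(values, class = c("feature_matrix", class(values)),
            transformed = transformed, centered = centered)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (transformed=%s, centered=%s)\n",
              nrow(x), ncol(x), attr(x, "transformed"), attr(x, "centered")))
  invisible(x)
}

#' Mean-center features within each subject
#'
#' Subtracts, for every subject and feature, the mean over that subject's
#' samples, removing stable inter-individual composition differences so the
#' classifier sees within-patient change. Subjects contributing a single
#' sample become all-zero rows (they are retained, not dropped).
#'
#' @param m a \code{feature_matrix} (samples x features, rownames = sample ids).
#' @param subject_map named character vector mapping sample id -> subject id;
#'   must cover every sample.
#' @return centered \code{feature_matrix}; per-subject column means are 0.
#' @export
subject_center <- function(m, subject_map) {
  ids <- rownames(m)
  if (is.null(ids) || !all(ids %in% names(subject_map)))
    stop("unmapped sample: every row must map to a subject")
  subj <- subject_map[ids]
  out <- unclass(m)
  for (s in unique(subj)) {
    rows <- which(subj == s)
    mu <- colMeans(out[rows, , drop = FALSE])
    out[rows, ] <- sweep(out[rows, , drop = FALSE], 2, mu)
  }
  feature_matrix(out, transformed = isTRUE(attr(m, "transformed")),
                 centered = TRUE)
}

#' Full preprocessing chain
#'
#' Fixed order: singleton removal, rarefaction, group-prevalence filter,
#' asinh transform, per-subject centering. Centering uses only each
#' subject's own samples, so it is independent of any later train/validation
#' split (subjects never straddle splits).
#'
#' @param table raw \code{otu_table}.
#' @param labels named active/remission labels (modeling samples only).
#' @param subject_map named sample id -> subject id vector.
#' @param depth rarefaction depth (default 4930).
#' @param threshold prevalence threshold (default 0.20).
#' @param seed seed for rarefaction.
#' @return list(features = centered feature_matrix, rarefied = otu_table,
#'   dropped = character vector of samples lost to rarefaction).
#' @export
preprocess <- function(table, labels, subject_map, depth = 4930,
                       threshold = 0.20, seed = NULL) {
  table <- subset_samples(table, intersect(sample_ids(table), names(labels)))
  table <- remove_singletons(table)
  rare <- rarefy(table, depth = depth, seed = seed)
  filt <- prevalence_filter(rare, labels, threshold = threshold)
  fm <- subject_center(asinh_transform(filt), subject_map)
  list(features = fm, rarefied = rare,
       dropped = attr(rare, "dropped_samples"))
}
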