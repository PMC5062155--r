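#' Chao1 richness estimate
#'
#' Bias-corrected by default: \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))},
#' where \eqn{F_1}/\eqn{F_2} are the numbers of OTUs seen exactly once/twice
#' in the sample; the corrected form stays defined when no doubletons exist.
#' The classic form \eqn{S_{obs} + F_1^2 / (2 F_2)} is available by flag.
#'
#' @param counts non-negative count vector for one sample; at least one
#'   positive entry.
#' @param bias_corrected use the (F2+1) denominator (default TRUE).
#' @return estimated richness, always >= observed richness.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (all(counts == 0)) stop("all-zero sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / 2  # classic form falls back when F2 = 0
}

#' Shannon entropy (nats)
#'
#' \eqn{-\sum p_i \ln p_i} over OTUs with positive count,
#' \eqn{p_i = c_i / \sum c}. Natural logarithm.
#'
#' @param counts non-negative count vector; at least one positive entry.
#' @return entropy in nats; 0 for a single-OTU sample, at most
#'   \eqn{\ln(S_{obs})}.
#' @export
shannon <- function(counts) {
  if (all(counts == 0)) stop("all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Per-sample alpha-diversity table
#'
#' @param table an \code{\link{otu_table}} (typically rarefied).
#' @return data.frame: sample_id, observed_otus, f1 (singletons within
#'   sample), f2 (doubletons), chao1, shannon.
#' @export
diversity_table <- function(table) {
  rows <- lapply(sample_ids(table), function(s) {
    x <- table$counts[s, ]
    data.frame(sample_id = s, observed_otus = sum(x > 0),
               f1 = sum(x == 1), f2 = sum(x == 2),
               chao1 = chao1(x), shannon = shannon(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-wise diversity summary
#'
#' Median and interquartile range of each index per activity group, plus a
#' Mann-Whitney (Wilcoxon rank-sum) p-value for the active-vs-remission
#' contrast. Quantiles use linear interpolation (R type 7).
#'
#' @param table rarefied \code{otu_table}.
#' @param labels named active/remission labels covering all samples.
#' @return data.frame with one row per index per group: index, group, n,
#'   median, q25, q75, p_mann_whitney (repeated within index).
#' @export
group_diversity_summary <- function(table, labels) {
  div <- diversity_table(table)
  grp <- labels[div$sample_id]
  if (any(is.na(grp))) stop("every sample must be labeled")
  for (g in c("active", "remission"))
    if (sum(grp == g) == 0) stop("group with zero samples: ", g)
  out <- list()
  for (index in c("chao1", "shannon")) {
    v <- div[[index]]
    p <- suppressWarnings(
      wilcox.test(v[grp == "active"], v[grp == "remission"], exact = FALSE)
    )$p.value
    if (is.na(p)) p <- 1  # fully tied groups: no evidence of a difference
    for (g in c("active", "remission")) {
      q <- quantile(v[grp == g], c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        index = index, group = g, n = sum(grp == g),
        median = q[2], q25 = q[1], q75 = q[3],
        p_mann_whitney = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
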