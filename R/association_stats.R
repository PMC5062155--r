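#' Per-group phylum prevalence
#'
#' A phylum is "present" in a sample iff any OTU assigned to it has a
#' positive count. Taxonomy strings are parsed at the requested Greengenes
#' rank prefix (\code{p__} for phylum); OTUs whose lineage lacks the rank
#' are pooled as "unclassified".
#'
#' @param table an \code{\link{otu_table}}.
#' @param labels named "active"/"remission" labels covering all samples.
#' @param rank taxonomic rank (default "phylum").
#' @return data.frame: taxon, n_active_present, n_active, frac_active,
#'   n_remission_present, n_remission, frac_remission.
#' @export
phylum_prevalence <- function(table, labels, rank = "phylum") {
  prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
                family = "f__", genus = "g__", species = "s__")
  if (!rank %in% names(prefixes)) stop("unknown rank: ", rank)
  taxon <- taxonomy_at_rank(table$taxonomy, prefixes[[rank]])
  ids <- sample_ids(table)
  grp <- labels[ids]
  if (any(is.na(grp))) stop("every sample must be labeled")
  present <- table$counts > 0
  out <- lapply(sort(unique(taxon)), function(tx) {
    in_tx <- present[, taxon == tx, drop = FALSE]
    pos <- rowSums(in_tx) > 0
    na <- sum(grp == "active"); nr <- sum(grp == "remission")
    pa <- sum(pos & grp == "active"); pr <- sum(pos & grp == "remission")
    data.frame(taxon = tx, n_active_present = pa, n_active = na,
               frac_active = pa / na, n_remission_present = pr,
               n_remission = nr, frac_remission = pr / nr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

taxonomy_at_rank <- function(taxonomy, prefix) {
  vapply(strsplit(taxonomy, ";"), function(parts) {
    parts <- trimws(parts)
    hit <- parts[startsWith(parts, prefix)]
    val <- if (length(hit) > 0) sub(prefix, "", hit[1], fixed = TRUE) else ""
    if (nzchar(val)) val else "unclassified"
  }, character(1))
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Uncorrected (no continuity correction), 1 degree of freedom:
#' \eqn{\chi^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}. Fisher's exact
#' two-sided test is available by flag.
#'
#' @param a,b,c,d cell counts: group-1 positive/negative, group-2
#'   positive/negative.
#' @param method "chisq" (default) or "fisher".
#' @return list(statistic, p); statistic is NA for Fisher.
#' @export
two_by_two_test <- function(a, b, c, d, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (method == "fisher") {
    p <- fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
    return(list(statistic = NA_real_, p = p))
  }
  if (any(margins == 0)) stop("zero margin: chi-square undefined")
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Friedman confounder screen over a feature panel
#'
#' For each feature, observations are averaged per (block, level) cell,
#' blocks (subjects) with every factor level observed are retained, and the
#' Friedman rank statistic across levels within blocks is computed with its
#' chi-square approximation. P-values are Benjamini-Hochberg adjusted across
#' features; the factor is declared non-confounding when no feature reaches
#' q < \code{fdr_alpha}.
#'
#' @param features numeric samples x features matrix (e.g. the panel).
#' @param factor_levels named factor/character per sample (e.g. medication
#'   on/off at sampling time).
#' @param subject_map named sample id -> subject id vector.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @return list(table = data.frame(feature, statistic, p, q),
#'   n_blocks_used, confounded, factor_levels_used).
#' @export
friedman_screen <- function(features, factor_levels, subject_map,
                            fdr_alpha = 0.05) {
  X <- unclass(features)
  ids <- rownames(X)
  lev <- as.character(factor_levels[ids])
  subj <- as.character(subject_map[ids])
  if (any(is.na(lev)) || any(is.na(subj)))
    stop("every sample needs a factor level and a subject")
  levels_all <- sort(unique(lev))
  if (length(levels_all) < 2) stop("factor must have >= 2 levels")
  # blocks usable only when the subject was observed under every level
  complete <- names(which(vapply(
    split(lev, subj), function(l) all(levels_all %in% l), logical(1))))
  if (length(complete) < 2) stop("fewer than 2 complete blocks")
  res <- lapply(colnames(X), function(f) {
    cell <- aggregate(X[subj %in% complete, f],
                      by = list(block = subj[subj %in% complete],
                                level = lev[subj %in% complete]),
                      FUN = mean)
    m <- matrix(NA_real_, length(complete), length(levels_all),
                dimnames = list(complete, levels_all))
    m[cbind(cell$block, cell$level)] <- cell$x
    ft <- friedman.test(m)
    stat <- unname(ft$statistic)
    p <- ft$p.value
    # all-tied data make the rank statistic 0/0; that is "no evidence
    # whatsoever", reported as statistic 0, p = 1
    if (!is.finite(stat)) { stat <- 0; p <- 1 }
    data.frame(feature = f, statistic = stat, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- p.adjust(tab$p, method = "BH")
  list(table = tab, n_blocks_used = length(complete),
       confounded = any(tab$q < fdr_alpha), factor_levels_used = levels_all)
}

#' Canonical correlation of a feature panel with fecal calprotectin
#'
#' With a univariate target the first canonical correlation equals the
#' multiple correlation of FC on the panel matrix, computed here by least
#' squares for numerical robustness. Because ~50 predictors on ~190 samples
#' overfit, the observed R is optimistic; inference rests on a permutation
#' test that shuffles FC across samples.
#'
#' @param features samples x panel numeric matrix.
#' @param fc fecal calprotectin per sample (named by sample id, or in row
#'   order), no missing values.
#' @param n_permutations permutation count (default 999).
#' @param seed RNG seed for the permutations.
#' @return list(r, p, n_permutations); p = (1 + #\{R_perm >= R_obs\}) /
#'   (1 + n_permutations).
#' @export
panel_fc_correlation <- function(features, fc, n_permutations = 999,
                                 seed = NULL) {
  X <- unclass(features)
  if (!is.null(names(fc))) fc <- fc[rownames(X)]
  fc <- as.numeric(fc)
  if (any(is.na(fc))) stop("FC must be non-missing for included samples")
  if (stats::sd(fc) == 0) stop("constant FC: correlation undefined")
  mult_r <- function(y) {
    fit <- lm.fit(cbind(1, X), y)
    yhat <- y - fit$residuals
    if (stats::sd(yhat) < 1e-12) return(0)
    max(0, stats::cor(yhat, y))
  }
  r_obs <- mult_r(fc)
  with_seed(seed, {
    r_perm <- vapply(seq_len(n_permutations),
                     function(i) mult_r(sample(fc)), numeric(1))
    list(r = r_obs,
         p = (1 + sum(r_perm >= r_obs)) / (1 + n_permutations),
         n_permutations = n_permutations)
  })
}
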