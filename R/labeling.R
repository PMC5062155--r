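#' Label disease activity from clinical measurements
#'
#' Applies the study's activity definitions: a sample is \emph{active} when
#' fecal calprotectin exceeds 250 ug/g; it is in \emph{remission} when
#' HBI <= 4 together with serum CRP < 5 mg/l and FC < 100 ug/g. Samples
#' meeting neither definition (notably FC in [100, 250] with quiescent
#' clinical scores) are \emph{indeterminate} and are excluded from modeling.
#' All inequalities are strict/non-strict exactly as stated; FC > 250 is
#' sufficient for active on its own, irrespective of HBI and CRP.
#'
#' @param hbi Harvey-Bradshaw index, non-negative integer score (vectorized).
#' @param crp serum C-reactive protein, mg/l, >= 0.
#' @param fc fecal calprotectin, ug/g, >= 0.
#' @return character vector in \{"active", "remission", "indeterminate"\};
#'   missing inputs yield "indeterminate".
#' @export
label_sample <- function(hbi, crp, fc) {
  n <- max(length(hbi), length(crp), length(fc))
  hbi <- rep_len(hbi, n); crp <- rep_len(crp, n); fc <- rep_len(fc, n)
  neg <- function(x) any(!is.na(x) & x < 0)
  if (neg(hbi) || neg(crp) || neg(fc))
    stop("negative clinical values: corrupt input")
  out <- rep("indeterminate", n)
  ok <- !is.na(hbi) & !is.na(crp) & !is.na(fc)
  out[ok & fc > 250] <- "active"
  out[ok & !(fc > 250) & hbi <= 4 & crp < 5 & fc < 100] <- "remission"
  out
}

#' Apply sample exclusions, then label
#'
#' Samples collected within one month (30 days) after a course of antibiotics
#' are marked \code{excluded} before any activity labeling; a missing
#' \code{days_since_antibiotics} never triggers the exclusion. Every sample
#' receives exactly one of the four labels.
#'
#' @param meta metadata data.frame as from \code{\link{read_metadata}}.
#' @param antibiotic_window days after an antibiotic course during which a
#'   sample is excluded (default 30).
#' @return data.frame(sample_id, subject_id, label) with label in
#'   \{active, remission, indeterminate, excluded\}.
#' @export
apply_exclusions <- function(meta, antibiotic_window = 30) {
  lab <- label_sample(meta$hbi, meta$crp, meta$fc)
  days <- meta$days_since_antibiotics %||% rep(NA_real_, nrow(meta))
  lab[!is.na(days) & days < antibiotic_window] <- "excluded"
  data.frame(sample_id = meta$sample_id, subject_id = meta$subject_id,
             label = lab, stringsAsFactors = FALSE)
}

# Labeled samples retained for modeling: active/remission only, as a named
# character vector (names = sample ids).
modeling_labels <- function(labels_df) {
  keep <- labels_df$label %in% c("active", "remission")
  setNames(labels_df$label[keep], labels_df$sample_id[keep])
}
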