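#' Specify a synthetic fecal-microbiota cohort
#'
#' The defaults mirror the reference study design: 71 subjects contributing
#' 1-8 samples each with the study's empirical frequency of samples per
#' subject (~194 samples in expectation), half of the samples active, a
#' long-tailed composition over 2000 OTUs of which 50 discriminate the two
#' states, and sequencing depths around 8333 reads truncated at the 4930
#' rarefaction depth so no synthetic sample is dropped by default.
#'
#' @param n_subjects number of subjects.
#' @param samples_per_subject_range integer (min, max) samples per subject.
#' @param samples_per_subject_probs optional probability vector over
#'   \code{min:max}; defaults to the study's empirical distribution when the
#'   range is the default 1-8, uniform otherwise.
#' @param n_otus total OTUs.
#' @param n_discriminatory OTUs carrying a state effect (<= n_otus).
#' @param effect_size multiplicative fold-change (>= 1) applied to
#'   discriminatory OTUs in active samples; half are up-weighted, half
#'   down-weighted. 1 means no signal.
#' @param subject_dispersion Dirichlet concentration of per-subject baseline
#'   compositions around the global profile (> 0; larger = subjects more
#'   alike).
#' @param depth_mean,depth_sd per-sample sequencing depth Normal parameters.
#' @param sparsity per-subject probability that an OTU is structurally
#'   absent, in [0, 1); the realized zero-cell fraction is higher because
#'   multinomial sampling adds zeros.
#' @param active_fraction target fraction of active samples in [0, 1].
#' @param min_depth lower truncation of drawn depths (default 4930, the
#'   rarefaction depth); set to 1 (\code{allow_shallow = TRUE}) to exercise
#'   the rarefaction-exclusion path.
#' @param allow_shallow convenience flag: overrides \code{min_depth} to 1.
#' @param seed RNG seed; same seed + same spec = bit-identical cohort.
#' @return validated \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_subjects = 71, samples_per_subject_range = c(1, 8),
                        samples_per_subject_probs = NULL, n_otus = 2000,
                        n_discriminatory = 50, effect_size = 4,
                        subject_dispersion = 50, depth_mean = 8333,
                        depth_sd = 1500, sparsity = 0.3,
                        active_fraction = 0.5, min_depth = 4930,
                        allow_shallow = FALSE, seed = 1) {
  if (allow_shallow) min_depth <- 1
  spec <- list(n_subjects = n_subjects,
               samples_per_subject_range = samples_per_subject_range,
               samples_per_subject_probs = samples_per_subject_probs,
               n_otus = n_otus, n_discriminatory = n_discriminatory,
               effect_size = effect_size,
               subject_dispersion = subject_dispersion,
               depth_mean = depth_mean, depth_sd = depth_sd,
               sparsity = sparsity, active_fraction = active_fraction,
               min_depth = min_depth, seed = seed)
  if (n_subjects < 1 || n_otus < 1 || n_discriminatory < 0)
    stop("counts must be positive")
  if (n_discriminatory > n_otus) stop("n_discriminatory must be <= n_otus")
  if (effect_size < 1) stop("effect_size must be >= 1")
  if (subject_dispersion <= 0) stop("subject_dispersion must be > 0")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction requires between 0 and all samples active")
  r <- samples_per_subject_range
  if (length(r) != 2 || r[1] < 1 || r[2] < r[1])
    stop("invalid samples_per_subject_range")
  if (is.null(spec$samples_per_subject_probs)) {
    spec$samples_per_subject_probs <- if (identical(as.numeric(r), c(1, 8))) {
      # study's empirical distribution: 14/71 single, 21 two, 19 three,
      # 8 four, 9 spread over five-to-eight
      c(14, 21, 19, 8, 9 / 4, 9 / 4, 9 / 4, 9 / 4) / 71
    } else {
      rep(1 / (r[2] - r[1] + 1), r[2] - r[1] + 1)
    }
  }
  if (length(spec$samples_per_subject_probs) != r[2] - r[1] + 1)
    stop("samples_per_subject_probs must have one entry per range value")
  class(spec) <- "cohort_spec"
  spec
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate tiny-alpha draw
  g / sum(g)
}

#' Generate a synthetic cohort
#'
#' Fixed, documented procedure: (1) a global long-tailed OTU profile is
#' drawn log-normally; (2) each subject receives a baseline composition
#' from a Dirichlet centered on the global profile with concentration
#' \code{subject_dispersion}, with structurally absent OTUs masked at rate
#' \code{sparsity}; (3) sample states are assigned to hit
#' \code{active_fraction} exactly (rounded); (4) in active samples the
#' discriminatory OTUs' relative abundances are multiplied (half) or
#' divided (half) by \code{effect_size} and renormalized; (5) counts are
#' multinomial at a Normal(depth_mean, depth_sd) depth truncated at
#' \code{min_depth}; (6) clinical metadata is drawn so activity labeling
#' reproduces the planted state exactly.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list(table = \code{otu_table}, metadata = data.frame,
#'   truth = character vector of discriminatory OTU ids).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    otu_ids <- sprintf("OTU_%04d", seq_len(spec$n_otus))
    profile <- rlnorm(spec$n_otus, meanlog = 0, sdlog = 2)
    profile <- profile / sum(profile)

    # plant effects in OTUs abundant enough to survive detection at the
    # rarefaction depth (expected count >= 5); fall back to the most
    # abundant remaining OTUs if too few qualify
    eligible <- which(profile * spec$min_depth >= 5)
    if (length(eligible) < spec$n_discriminatory)
      eligible <- order(profile, decreasing = TRUE)[
        seq_len(min(spec$n_otus, max(spec$n_discriminatory, 1)))]
    disc <- sort(sample(eligible, spec$n_discriminatory))
    n_up <- ceiling(spec$n_discriminatory / 2)
    up <- disc[seq_len(n_up)]
    down <- setdiff(disc, up)

    r <- spec$samples_per_subject_range
    n_samples_per_subject <- sample(r[1]:r[2], spec$n_subjects, replace = TRUE,
                                    prob = spec$samples_per_subject_probs)
    n_total <- sum(n_samples_per_subject)
    subject_ids <- sprintf("P%03d", seq_len(spec$n_subjects))
    subj_of_sample <- rep(subject_ids, n_samples_per_subject)
    sample_ids <- sprintf("S%04d", seq_len(n_total))

    n_active <- round(spec$active_fraction * n_total)
    state <- rep("remission", n_total)
    state[sample(n_total, n_active)] <- "active"

    baselines <- matrix(0, spec$n_subjects, spec$n_otus,
                        dimnames = list(subject_ids, otu_ids))
    for (s in seq_len(spec$n_subjects)) {
      base <- rdirichlet1(spec$subject_dispersion * profile)
      mask <- runif(spec$n_otus) < spec$sparsity
      mask[which.max(base)] <- FALSE  # never empty a subject entirely
      base[mask] <- 0
      baselines[s, ] <- base / sum(base)
    }

    counts <- matrix(0, n_total, spec$n_otus,
                     dimnames = list(sample_ids, otu_ids))
    depth_raw <- round(rnorm(n_total, spec$depth_mean, spec$depth_sd))
    depths <- pmax(depth_raw, max(1, spec$min_depth))
    for (i in seq_len(n_total)) {
      rel <- baselines[subj_of_sample[i], ]
      if (state[i] == "active" && spec$effect_size > 1) {
        rel[up] <- rel[up] * spec$effect_size
        rel[down] <- rel[down] / spec$effect_size
        rel <- rel / sum(rel)
      }
      counts[i, ] <- rmultinom(1, size = depths[i], prob = rel)
    }

    clin <- clinicals_from_state(state)
    metadata <- data.frame(
      subject_id = subj_of_sample, sample_id = sample_ids,
      hbi = clin$hbi, crp = clin$crp, fc = clin$fc,
      days_since_antibiotics = NA_real_,
      biologicals = rbinom(n_total, 1, 0.6),
      mesalazine = rbinom(n_total, 1, 0.12),
      thiopurine = rbinom(n_total, 1, 0.4),
      location = rep(sample(c("L1", "L2", "L3"), spec$n_subjects,
                            replace = TRUE, prob = c(0.32, 0.24, 0.44)),
                     n_samples_per_subject),
      colectomy = rep(rbinom(spec$n_subjects, 1, 0.085),
                      n_samples_per_subject),
      age = rep(round(runif(spec$n_subjects, 18, 70)),
                n_samples_per_subject),
      depth = depths, state = state, stringsAsFactors = FALSE)

    taxonomy <- setNames(synthetic_taxonomy(spec$n_otus), otu_ids)
    list(table = otu_table(counts, taxonomy), metadata = metadata,
         truth = otu_ids[disc])
  })
}

# Plausible Greengenes-style lineages for synthetic OTUs; drawn with the
# current RNG so cohorts remain fully seed-determined.
synthetic_taxonomy <- function(n) {
  phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Actinobacteria", "Fusobacteria", "Verrucomicrobia")
  w <- c(0.40, 0.42, 0.08, 0.04, 0.03, 0.03)
  px <- sample(phyla, n, replace = TRUE, prob = w)
  sprintf("k__Bacteria; p__%s; c__; o__; f__; g__; s__", px)
}

#' Draw clinical values consistent with a disease state
#'
#' Active samples draw FC uniformly in (259, 4900) ug/g (so FC > 250 holds
#' always) with HBI and CRP spanning the active ranges; remission samples
#' draw HBI in 0-4, CRP in (0, 4.7) mg/l and FC in (14, 98) ug/g. By
#' construction \code{\link{label_sample}} recovers the state exactly.
#'
#' @param state character vector of "active"/"remission".
#' @return data.frame(hbi, crp, fc), one row per state entry. Uses the
#'   current RNG state (callers seed).
#' @export
clinicals_from_state <- function(state) {
  if (!all(state %in% c("active", "remission")))
    stop("unknown state: ", paste(setdiff(state, c("active", "remission")),
                                  collapse = ", "))
  n <- length(state)
  act <- state == "active"
  hbi <- ifelse(act, sample(0:15, n, replace = TRUE),
                sample(0:4, n, replace = TRUE))
  crp <- ifelse(act, runif(n, 0.9, 30), runif(n, 0, 4.7))
  fc <- ifelse(act, runif(n, 259, 4900), runif(n, 14, 98))
  data.frame(hbi = hbi, crp = round(crp, 1), fc = round(fc, 1))
}
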