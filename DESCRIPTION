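Package: otupanel
Title: Subject-Blocked Random-Forest OTU Panels for Disease-Activity Classification
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies Crohn's disease activity (active flare versus remission)
    from fecal 16S OTU count tables with repeated samples per patient. Implements
    clinical activity labeling from HBI, serum CRP and fecal calprotectin;
    preprocessing (singleton removal, seeded rarefaction, group-prevalence
    filtering, inverse-hyperbolic-sine transform, per-subject mean centering);
    alpha diversity (bias-corrected Chao1, Shannon); a two-stage subject-blocked
    repeated-subset random forest (panel selection by averaged Gini importance,
    majority-vote classification, ROC/AUC, proximity PCA); supporting statistics
    (phylum prevalence contrasts, Friedman confounder screening with
    Benjamini-Hochberg FDR, permutation-tested canonical correlation with fecal
    calprotectin); and a seedable Dirichlet-multinomial cohort simulator so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
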