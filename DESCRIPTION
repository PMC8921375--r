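Package: bprm
Title: Bullous Parametric Response Mapping of Paired Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies emphysema and functional small-airway disease (fSAD)
    from paired inspiratory/expiratory chest CT. Segments lungs and airways,
    partitions upper and lower lobe groups via Hessian fissure detection and
    thin-plate-spline surfaces, co-registers the expiratory scan with coherent
    point drift and landmark warping, classifies voxels with a parametric
    response map (PRM), extracts low attenuation clusters (LAC) by iterative
    erosion with core splitting, and fits a scale-and-region linear model of
    airflow limitation (FEV1/FVC%) with backward selection and repeated
    cross-validation. The fitted model is localized on a lung grid as the
    bullous parametric response map (BPRM). Includes a synthetic phantom and
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
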