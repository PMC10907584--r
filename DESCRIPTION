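Package: pvsbedrest
Title: Perivascular Space Morphometry, DTI-ALPS and Longitudinal Group
    Analysis for Bed-Rest Neuroimaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects MRI-visible perivascular spaces (MV-PVS) in white
    matter from T1-weighted volumes using a local-intensity heterogeneity
    rule with 3D corner-connectivity clustering, computes per-cluster and
    per-subject morphometric summaries normalised to white-matter volume,
    fits diffusion tensors from diffusion-weighted volumes and derives the
    DTI-ALPS diffusivity index from spherical regions of interest, and fits
    longitudinal group-by-time linear models for head-down-tilt bed-rest
    cohorts stratified by spaceflight-associated neuro-ocular syndrome
    (SANS) status. Includes seed-reproducible synthetic-data generators
    (tubular T1 phantoms, tensor-field DWI, longitudinal cohort tables) so
    the full pipeline can be exercised and validated without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
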