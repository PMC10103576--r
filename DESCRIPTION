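Package: eamsim
Title: Simulated Substrate Electroanatomic Mapping in Infarcted Ventricular Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates substrate electroanatomic mapping (EAM) in synthetic
    post-infarct left-ventricular models. Builds idealized voxelized LV
    geometries with ventricular coordinates, rule-based fibres and
    triangulated endo/epicardial mapping surfaces; generates infarct
    substrates (dense core plus border zone) with conducting channels;
    runs monodomain propagation with a two-variable ionic model under
    S1/S2 pacing protocols and programmed-stimulation VT induction;
    computes unipolar electrograms by a volume-conductor forward model;
    extracts six EAM features (voltage amplitude, conduction velocity,
    isochronal crowding, fractionation index, electrogram duration,
    frequency power); and evaluates how multi-wavefront and decremental
    pacing improve detection of infarct remodelling and critical
    ventricular-tachycardia circuit sites via map concordance and
    incremental logistic-regression ladders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
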