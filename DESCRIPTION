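Package: fedlesion
Title: Federated Simulation of Volumetric Lesion Segmentation with
    Ability-Weighted Aggregation and Lesion-Volume Loss Re-Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-process simulation of federated training for 3-D lesion
    segmentation across clients with heterogeneous image appearance and lesion
    burden. Implements the FedMSRW strategy: server-side aggregation of the
    non-normalization parameters weighted by each client's segmentation
    ability, and client-side re-weighting of the soft Dice loss by the inverse
    lesion-volume ratio, alongside FedAvg, FedBN and FedProx baselines. Ships
    a compact 3-D encoder-decoder network with batch normalization (forward
    and backward passes implemented natively), a multi-client 3-D brain
    phantom generator with controllable domain shift, patch-tiled whole-volume
    inference, case-level and voxel-level Dice evaluation, and an N-fold
    cross-validation driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
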