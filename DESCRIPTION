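Package: dmsdecode
Title: Population Decoding of Stimulus and Choice in Delayed
    Match-to-Sample Spiking Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Time-resolved linear-discriminant decoding of visual stimulus
    identity and forthcoming behavioral choice from multi-channel spiking
    activity recorded (or simulated) during a delayed match-to-sample task.
    Provides an inhomogeneous-Poisson session simulator with known
    ground-truth coding structure, causal moving-window firing-rate binning,
    repeated stratified cross-validation with cubic-spline interpolation and
    chance-crossing latency estimation, a correct-to-error cross-condition
    generalization test, and supervised identification of stimulus and
    decision subspaces with principal-angle and silhouette diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
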