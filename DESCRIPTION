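Package: landmarker
Title: Landmark Gene Discovery from Expression Compendia with Autoencoders
    and DeepLIFT Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven pipeline for selecting landmark genes from bulk or
    single-cell expression matrices. An autoencoder with a narrow bottleneck is
    trained to capture nonlinear inter-gene structure; DeepLIFT Rescale-rule
    attribution scores every input gene's influence on the bottleneck units;
    the top-k genes by average absolute contribution form a landmark set; and a
    feed-forward regressor infers target-gene expression from the landmarks.
    Includes quantile normalization to a fixed range, k-means based profile
    deduplication, seeded train/test splitting, per-gene MAE/PCC evaluation
    with a cross-gene permutation test, paired comparison of landmark sets,
    and a seeded synthetic-data generator with known driver/follower/noise
    gene structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    mclust,
    cluster
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
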