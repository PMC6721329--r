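Package: posturecluster
Title: Unsupervised Clustering of Spinal Posture Change from Wearable Tilt Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for postural-training studies that record the
    lumbar spine with a five-sensor accelerometer wearable. From databases of
    timestamped tilt-angle snapshots it extracts per-user before/after posture
    pairs, reconstructs two-dimensional spine curves from the tilt angles via
    circular-arc chains, derives a 15-dimensional geometric change feature per
    pair, embeds the features with principal component analysis followed by
    t-distributed stochastic neighbor embedding, clusters the resulting map by
    cutting the heaviest edges of its Euclidean minimum spanning tree, and
    profiles each cluster as a bundle of offset spine shapes with percentile
    bands. Includes per-sensor paired Wilcoxon signed-rank tests with an exact
    small-sample path, a synthetic snapshot-database generator with planted
    change archetypes for end-to-end validation, and a perplexity-stability
    sweep for the embedding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
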