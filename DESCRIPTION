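Package: stsmap
Title: Object-Centered Normalization, Clustering and Mapping of Sit-to-Stand Behaviors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for natural sit-to-stand behavior recorded with
    depth cameras in living spaces. Skeleton trajectories are re-expressed in a
    seat-anchored ("object-centered") coordinate system built from least-squares
    plane fits of the seat surface and backrest, so behaviors from different
    seats and camera placements become comparable. Behaviors are time-normalized
    by cubic-spline resampling, compared with per-joint Manhattan trajectory
    distances, clustered hierarchically (UPGMA or Ward) with silhouette-based
    selection of the cluster count, summarized as cluster-average motions, and
    embedded in a two-dimensional map by stress-minimizing multidimensional
    scaling. Includes a synthetic-data generator emulating seat scans and two
    standing-behavior archetypes (armrest-assisted and forward-lean), plus a
    24-trial study-composition library, so the whole pipeline runs without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ggplot2
Config/testthat/edition: 3
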