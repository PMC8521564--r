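Package: recureig
Title: Recurrence Eigenvalues of Convolutional Fuzzy Recurrence Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the complexity of movement time series (C. elegans
    eigenworm traces, human gait swing intervals) by the largest eigenvalue of
    a convolutional fuzzy recurrence plot. A scalar series is reconstructed in
    phase space by time-delay embedding, partitioned by fuzzy c-means, and
    turned into a fuzzy recurrence plot via max-min composition of cluster
    memberships; iterated sharpening convolution, rectification and max
    pooling reduce the plot to a small matrix whose largest eigenvalue is the
    complexity statistic. Includes a sample-entropy baseline, gait
    preprocessing (third-order median filter, truncation), cohort summaries
    (t-based p-values and confidence intervals), UPGMA dendrograms over cohort
    distances, readers for label-prefixed series tables and multi-column gait
    records, a seeded synthetic cohort generator, and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
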