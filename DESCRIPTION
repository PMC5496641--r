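Package: chromsig
Title: Multichannel Chromatin Signatures: Re-Orientation, Spectral
    Clustering and Genome-Wide Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes the multichannel chromatin landscape (several
    histone-modification ChIP-seq tracks, possibly at several time points)
    around a set of anchor loci.  Signatures are extracted as channel-by-
    position matrices from binned signal tracks, given a strand by an
    iterative Max-Max re-orientation algorithm, grouped by spectral
    clustering on summed per-channel Gaussian-kernel adjacencies with
    empirically calibrated bandwidths, and each cluster's mean signature
    can then be slid across the genome to find new loci with a matching
    chromatin state, scoring windows by Pearson correlation regularized by
    an empirical signal-height prior.  Includes a synthetic-track
    generator with planted promoter-like, enhancer-like and featureless
    signatures for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
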