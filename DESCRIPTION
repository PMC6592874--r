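Package: ieegbids
Title: Read, Write, Validate and Simulate iEEG-BIDS Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tooling for the intracranial electroencephalography (iEEG)
    extension of the Brain Imaging Data Structure (BIDS). Parses and
    constructs BIDS filenames and entity sets, reads and writes the two
    compliant iEEG signal formats (European Data Format and the
    BrainVision Core Data Format) with bit-exact roundtrips, models the
    iEEG sidecar metadata files (_ieeg.json, _channels.tsv,
    _electrodes.tsv, _coordsystem.json, _events.tsv), validates whole
    dataset trees including cross-file consistency rules such as
    coordinate-system pairing and channel/electrode agreement, and
    generates seeded synthetic datasets for five canonical iEEG study
    archetypes together with corruption operators for negative testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
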