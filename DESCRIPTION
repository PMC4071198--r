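Package: refasset
Title: Declarative Reference-Data Asset Management with Provenance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standalone manager for the reference data that sequence-analysis
    tools depend on (genome FASTA files, aligner indexes and similar assets).
    Declarative recipes describe how an asset is built; the engine runs them in
    an isolated staging directory with a JSON parameter bundle in and a JSON
    entry bundle out, finalizes raw values via value translations, installs
    files under a managed data root, and appends entries atomically to live
    data-table registries persisted as tab-separated location (.loc) files --
    no restart required. Every run is recorded with parameters, timestamps,
    a sha256 file manifest and the captured log, so installed assets can be
    verified for tampering and whole runs replayed elsewhere.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    digest,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
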