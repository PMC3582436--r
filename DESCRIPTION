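Package: pfff
Title: Probabilistic Fast File Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes keyed file fingerprints from a pseudorandom sample of
    blocks instead of a full scan, so that hashing time does not grow with
    file size. Under the delta-variability assumption (any two meaningfully
    distinct same-length files differ in at least a delta fraction of their
    blocks) the collision probability is provably bounded, and the package
    provides the calculators connecting the sample count, the collision
    budget and the collection size. Includes exact and sampled estimators of
    the delta statistic between files, a duplicate-detection mode framed as
    a statistical hypothesis test, random-access byte sources over local
    files and HTTP(S) URLs (range queries, so remote files are fingerprinted
    without download), a synthetic-collection generator with exactly
    controlled pairwise block differences for offline validation of the
    probabilistic guarantees, and a command-line front end with
    checksum-tool ergonomics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    curl,
    jsonlite,
    openssl,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    callr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
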