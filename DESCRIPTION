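Package: qzkit
Title: Read, Inspect, and Create QIIME 2 Artifact Archives Without QIIME 2
Version: 0.1.0
Authors@R:
    person("Q.", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A standalone toolkit for QIIME 2 artifact archives (.qza) and
    visualization artifacts (.qzv). Artifacts are ZIP containers with a single
    UUID-named root directory holding data payloads, structured metadata
    (semantic type and data format), an md5 checksum manifest, and an embedded
    provenance tree recording every ancestor artifact and action. qzkit reads
    and validates these archives, reconstructs the provenance DAG and emits it
    as a terminal listing or Graphviz DOT text, merges and deduplicates the
    BibTeX citations carried by a set of artifacts, extracts data payloads with
    a filename-inheriting renaming convention, streams text payloads, and
    packages static HTML report directories as new visualization artifacts --
    all without a QIIME 2 installation. Includes a seeded generator of
    structurally valid synthetic artifacts used as the test oracle, and a
    command-line entry point with six subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    stats,
    tools,
    utils,
    yaml,
    zip
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
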