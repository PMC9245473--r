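---
title: "Anatomy of a QIIME 2 artifact, and how qzkit handles it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy of a QIIME 2 artifact, and how qzkit handles it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qzkit)
```

## The archive data model

A QIIME 2 artifact is a ZIP archive with a single top-level directory named
by the artifact's UUID. Under that root:

```
<uuid>/
  VERSION          "QIIME 2" banner, "archive: N", "framework: V"
  metadata.yaml    uuid, type (semantic type), format (data format)
  checksums.md5    md5sum-style manifest (archive dialect >= 5)
  data/            the payload: FASTA/FASTQ(.gz)/BIOM/TSV/Newick, or an
                   HTML tree for visualizations
  provenance/      metadata.yaml + action/action.yaml + citations.bib for
                   the focal artifact, and artifacts/<uuid>/... repeating
                   that layout for every ancestor
```

Two attributes define what the payload *is*: the **semantic type**
(`FeatureData[Sequence]`, `FeatureTable[Frequency]`, `Visualization`, ...)
and the **data format** (the on-disk layout, e.g. a directory of FASTA
files). Visualizations record a literal `null` format, which qzkit maps to
`NA`.

### Archive-version dialects

Frameworks of different releases write mutually incompatible archives, so
qzkit surfaces both versions rather than hiding them, accepts archive
versions >= 2, and treats `checksums.md5` as required from version 5 onward
but optional below — older archives still load, and
`qz_verify_checksums()` on them raises a distinct *unsupported* condition
rather than pretending verification passed. This floor is our own decision:
the original tooling never documents which dialects it accepts, and a reader
should degrade gracefully rather than refuse history.

### Validation posture

UUID validation is purely syntactic (the 8-4-4-4-12 hex pattern, case
folded to lowercase); the version nibble is not enforced on read, because
real-world archives are more varied than the spec of any one release.
Member paths that are absolute or contain `..` are rejected outright as a
hardening measure. When file extension (`.qza`/`.qzv`) and semantic type
disagree, metadata wins and a warning is attached to the loaded object —
the extension is a convention, the metadata is the record. Every error is a
classed condition (`qz_malformed_error`, `qz_integrity_error`,
`qz_version_error`, ...) so batch callers can distinguish failure modes.

## Provenance reconstruction

`qz_build_graph()` reads the focal metadata/action pair plus one
`artifacts/<uuid>/` subtree per ancestor, and draws one edge per recorded
action input, **ancestor → consumer**, labelled with the input parameter
name. Arrow direction is our choice (the source material never states it):
data flows forward, inputs feed products, matching how such graphs are
conventionally drawn.

Determinism choices, all motivated by making output diffable and testable:

- listing and DOT emit nodes in **topological order**, ties broken by
  C-locale lexicographic UUID order;
- `qz_to_dot()` is byte-deterministic for a given graph; node identifiers
  are full UUIDs, labels carry the semantic type over an 8-character UUID
  prefix (full UUID in the tooltip) for legibility;
- acyclicity is asserted on every constructed graph — a cycle means a
  corrupt archive and raises rather than looping.

An input UUID with no corresponding ancestor subtree (a truncated archive)
becomes a *stub node* plus a warning instead of a hard failure: the listing
must remain useful on imperfect real-world data. Action parameters and
execution-environment details are hidden behind `verbose = TRUE`; the
default listing shows the property set users actually scan (uuid, type,
format, action kind, plugin:action). Unknown action kinds are kept verbatim
with a fallback flag rather than rejected, since plugin ecosystems grow.

## Citations and deduplication

The BibTeX parser is deliberately **brace-counting, not field-aware**:
everything between the outer braces is preserved verbatim (no re-wrapping,
no key case-folding), which is the only safe way to round-trip arbitrary
BibTeX emitted by heterogeneous tools. Unbalanced braces raise with the
byte offset of the offending record.

Two entries are duplicates when they share a **citation key OR a
whitespace-normalized body**. Rationale: QIIME 2 keys embed plugin/version
strings that are stable across one pipeline's artifacts (key match catches
those), while the same reference can appear under different keys in
different plugins (body match catches those). Same key with a *different*
body keeps the first entry and warns — silently dropping a conflicting
record would hide real divergence. Merging covers the focal artifact *and*
all its ancestors' `citations.bib` files; we read "all citations" as the
full ancestor set, since a bibliography for an analysis must credit every
step, not just the last one.

## Extraction semantics

The renaming rule: an artifact with **one** data file extracts directly as
`<artifact-basename><payload extension>`, where the compound extension is
everything from the payload's first dot (`.fastq.gz` stays whole —
downstream tools key on full suffixes). Anything with several files, and
every visualization (an HTML page is only meaningful as a tree), extracts
into a directory named after the artifact, preserving the `data/`-relative
subtree. A lone file nested inside a subdirectory still counts as the
single-file case and is flattened — the intent of the convention is one
artifact → one conveniently named file; whether the original tool flattens
here cannot be confirmed from its description, so this is a documented,
possibly divergent choice. Overwrite protection is default-on with an
explicit `force`; basename collisions between inputs abort before any byte
is written. Extracted content is re-verified against the manifest md5 when
one exists.

`qz_view()` streams one text member: `.gz` members are gunzipped first, and
anything with a NUL byte in its first 4096 bytes is refused as binary
(there is no principled definition of "text file"; the NUL sniff is the
conventional one). `raw = TRUE` disables *both* the decompression and the
sniff — that is what makes streaming exactly equal to extraction,
byte-for-byte, an invariant the tests assert.

## Creating visualizations

`qz_make_visualization()` targets archive version 5 (the newest dialect,
with a manifest) and requires `index.html` at the top of the input
directory because viewers open `data/index.html` by convention. Provenance
is minimal but honest: an import-kind action recording the source directory
(and an optional note) plus the toolkit's own citation — enough for a
well-formed tree without inventing history. Per-tree `VERSION` copies are
included to match the layout framework-written archives carry; acceptance
by any specific live QIIME 2 release is an aspiration we cannot test at the
desk and do not promise. Dot-prefixed files are skipped by default (editor
droppings do not belong in shipped reports). Output is atomic — staged,
zipped to a temp file, renamed — so a failure never leaves a corrupt
half-archive. Byte-determinism is *not* promised here (fresh UUID, real
timestamps); structural determinism is.

## The synthetic fixtures, and what a green test proves

`qz_standard_suite()` generates ten artifacts: six well-formed (import-only,
single-file FASTA, four-file gzipped FASTQ, a three-step
import→denoise→classify chain, a diamond-shaped ancestry, and an HTML
visualization) and four corrupt in precisely one way each (two top-level
roots, root/metadata UUID mismatch, one flipped payload byte, truncated
VERSION). UUIDs come from a seeded generator and file timestamps are pinned,
so generation is **byte-deterministic per seed** — the returned record
(UUIDs, adjacency, citation keys, payload digests) is the ground truth every
test compares against, and md5 assertions use `tools::md5sum` as an oracle
independent of the `digest`-based implementation path.

What the fixtures emulate: the container format, its metadata dialects, its
provenance layout, realistic file names and tiny valid-looking payloads.
What they do **not** emulate: semantically meaningful microbiome data,
every historical archive-version quirk, or archives written by actual
framework releases. A green suite therefore establishes structural
correctness of reading, reconstruction, merging, extraction and writing —
not behavioural equality with any specific QIIME 2 version.

## Known limitations

- No writing or repair of regular (`.qza`) artifacts; no semantic
  validation of payloads (a FASTA that does not parse still extracts).
- No diffing of provenance between artifacts, and no attempt to replicate
  the hosted provenance viewer's semantics.
- PDF rendering is a pass-through to an external `dot` binary; when absent,
  the CLI degrades with a clear message and nonzero status.
- Multi-gigabyte payloads are read member-at-a-time into memory on
  extraction; listing never touches payload bytes, but extraction is not
  streamed.
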