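# qzkit

Work with QIIME 2 artifact archives — list, extract, cite, trace provenance,
view, and create — **without a QIIME 2 installation**.

## The problem

QIIME 2, the dominant platform for metabarcoding (16S/18S/ITS amplicon)
analysis, exchanges data as *artifacts*: ZIP containers (`.qza` for datasets,
`.qzv` for HTML visualizations) whose single root directory is named by a
UUID and holds, alongside the data payload, rich structured metadata — the
artifact's *semantic type* (e.g. `FeatureData[Sequence]`) and *data format*,
an md5 checksum manifest, the BibTeX citations for every tool used, and the
full provenance of every ancestor artifact back to the initial import.

That metadata makes analyses shareable and reproducible, but the only
official way to read it requires the full QIIME 2 framework. Collaborators
doing downstream analysis with other toolkits, and pipeline authors who just
need a feature table or a bibliography, are stuck. qzkit is a lightweight,
dependency-minimal reader (and, for visualizations, writer) of the artifact
container itself:

- **list** — tabular (strict TSV) summary of many artifacts at once: file,
  UUID, type, format, and with `--all` the archive/framework versions,
  payload and ancestor counts.
- **extract** — payloads copied out with a convenient renaming convention:
  a single-file artifact `rep-seqs.qza` becomes `rep-seqs.fasta`; multi-file
  artifacts and visualizations get a directory named after the archive.
- **cite** — the BibTeX citations of a set of artifacts (including all
  their ancestors), merged and de-duplicated: a ready bibliography for a
  complete analysis.
- **provenance** — the ancestry DAG reconstructed from the embedded
  provenance tree, printed as a topologically sorted listing or emitted as
  deterministic Graphviz DOT (PDF via the external `dot` program when
  available).
- **view** — stream a text payload (transparently gunzipped) to stdout.
- **make** — package any static HTML report directory as a structurally
  valid `.qzv`, letting non-QIIME pipelines ship multi-file reports as a
  single checksummed archive.

A seeded synthetic-artifact generator (`qz_standard_suite()`) doubles as the
test oracle and as a demo data source; no real QIIME 2 output is needed
anywhere.

## Worked example

```r
library(qzkit)
d <- file.path(tempdir(), "demo")
recs <- qz_standard_suite(d, seed = 7)   # writes 10 synthetic artifacts
qz_cli(c("list", "--basename", recs$single_file$path,
         recs$chain$path, recs$visualization$path))
```

```
file	uuid	type	format
rep-seqs.qza	f3003be9-842d-4dfa-b0f7-9e38c203bb33	FeatureData[Sequence]	DNASequencesDirectoryFormat
taxonomy.qza	498c0a7e-8b6b-473f-a6d2-618a1e54e3db	FeatureData[Taxonomy]	TSVTaxonomyDirectoryFormat
summary.qzv	65ad36eb-2dc7-40c7-ad9f-b90d3cbddc7c	Visualization	-
```

One row per artifact: its UUID, semantic type, and data format (`-` marks
the null format of visualizations). The taxonomy artifact's history:

```r
qz_cli(c("provenance", recs$chain$path))
```

```
69a6192e-b203-4bf6-b3eb-30b0a45051da	SampleData[SequencesWithQuality]	SingleLanePerSampleSingleEndFastqDirFmt	import	-	
5c91f508-a9d5-4c44-9d27-89e084532f17	FeatureData[Sequence]	DNASequencesDirectoryFormat	method	dada2:denoise-single	
498c0a7e-8b6b-473f-a6d2-618a1e54e3db	FeatureData[Taxonomy]	TSVTaxonomyDirectoryFormat	method	feature-classifier:classify-sklearn	*
```

Ancestors print before descendants: raw reads were imported, denoised with
DADA2 into representative sequences, then classified; `*` marks the focal
artifact. `qz_build_graph()` returns the same DAG programmatically and
`qz_to_dot()` renders it as Graphviz source. The same archives verify
(`qz_verify_checksums()` returns a zero-row mismatch table), extract, and
yield a merged bibliography via `qz_merge_citations()`.

The shell entry point is installed at
`system.file("exec", "qzkit", package = "qzkit")`.

## Documentation

The methods vignette (`vignettes/artifact-anatomy.Rmd`) describes the
archive data model, the DAG reconstruction and its determinism guarantees,
the deduplication rule for citations, the renaming convention for
extraction, and exactly what the synthetic fixtures do and do not emulate.
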