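# Synthetic artifact generator: the test oracle.
#
# Fixtures are structurally valid artifacts with fully known metadata,
# payloads, ancestry, and citations, generated hermetically (no network, no
# Qiime2) from a declarative chain specification. UUIDs are drawn from a
# seeded generator and every staged file gets a fixed mtime, so generation is
# byte-deterministic for a given seed — two runs of the same spec produce
# identical archives. The returned record (uuids, adjacency, citation keys,
# payload digests) is the ground truth that the provenance, bibliography,
# and extraction tests compare against.

FIXTURE_MTIME <- as.POSIXct("2021-03-03 12:00:00", tz = "UTC")

with_preserved_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Describe one node of a fixture ancestry chain
#'
#' @param semantic_type Semantic type text (e.g. `"FeatureData[Sequence]"`).
#' @param data_format Data format text, or `NULL` for visualizations.
#' @param payloads Named list of payload contents (character or raw), names
#'   are `data/`-relative paths. Only the focal (last) node's payloads are
#'   written. A character payload under a `.gz` name is gzip-compressed.
#' @param action_kind `"import"`, `"method"`, `"visualizer"`, `"pipeline"`.
#' @param plugin,action Plugin and action names recorded in action.yaml.
#' @param inputs Named integer vector: input parameter name -> 1-based chain
#'   index of the ancestor node (must point to an earlier position).
#' @param parameters Named character vector of action parameters.
#' @param citations Character vector of citation keys carried by the node's
#'   citations.bib (bodies are derived deterministically from the keys).
#' @return A `qz_fixture_node` specification.
#' @export
qz_fixture_node <- function(semantic_type, data_format = NULL,
                            payloads = list(), action_kind = "method",
                            plugin = NULL, action = NULL,
                            inputs = integer(), parameters = character(),
                            citations = character()) {
  if (identical(action_kind, "import") && length(inputs) > 0L) {
    qz_error("qz_fixture_error", "an import node cannot have inputs")
  }
  structure(
    list(semantic_type = semantic_type, data_format = data_format,
         payloads = payloads, action_kind = action_kind, plugin = plugin,
         action = action, inputs = inputs, parameters = parameters,
         citations = citations),
    class = "qz_fixture_node"
  )
}

#' Assemble a fixture specification
#'
#' @param nodes List of [qz_fixture_node()] in chain order; the final node is
#'   the focal artifact written to disk, earlier nodes become its recorded
#'   ancestors.
#' @param seed Integer seed driving uuid generation.
#' @param archive_version Archive format version to write (manifest included
#'   at >= 5).
#' @return A `qz_fixture_spec`.
#' @export
qz_fixture_spec <- function(nodes, seed = 1L, archive_version = 5L) {
  stopifnot(length(nodes) >= 1L)
  for (i in seq_along(nodes)) {
    stopifnot(inherits(nodes[[i]], "qz_fixture_node"))
    refs <- nodes[[i]]$inputs
    if (length(refs) && any(refs >= i | refs < 1L)) {
      qz_error("qz_fixture_error",
               sprintf("node %d references chain position %d (only earlier positions allowed)",
                       i, refs[refs >= i | refs < 1L][1L]))
    }
  }
  structure(
    list(nodes = nodes, seed = as.integer(seed),
         archive_version = as.integer(archive_version)),
    class = "qz_fixture_spec"
  )
}

fixture_citation_body <- function(key) {
  sprintf("\n  title = {Reference {%s}},\n  journal = {Synthetic Fixtures},\n  year = {2021}\n",
          key)
}

fixture_action_yaml <- function(node, uuids) {
  a <- list(type = node$action_kind)
  if (!is.null(node$plugin)) a$plugin <- node$plugin
  if (!is.null(node$action)) a$action <- node$action
  if (length(node$inputs)) {
    a$inputs <- lapply(seq_along(node$inputs), function(k) {
      stats::setNames(list(uuids[[node$inputs[[k]]]]), names(node$inputs)[k])
    })
  }
  if (length(node$parameters)) {
    a$parameters <- lapply(seq_along(node$parameters), function(k) {
      stats::setNames(list(unname(node$parameters[[k]])),
                      names(node$parameters)[k])
    })
  }
  yaml::as.yaml(list(action = a))
}

payload_bytes <- function(name, content) {
  bytes <- if (is.raw(content)) content else charToRaw(enc2utf8(content))
  if (grepl("\\.gz$", name) && !is.raw(content)) {
    bytes <- memCompress(bytes, type = "gzip")
  }
  bytes
}

write_node_tree <- function(dir, node, uuid, uuids, framework_version) {
  write_text(file.path(dir, "metadata.yaml"),
             metadata_text(uuid, node$semantic_type, node$data_format))
  write_text(file.path(dir, "VERSION"), version_text(framework_version))
  if (length(node$citations)) {
    entries <- lapply(node$citations, function(k) {
      qz_citation("article", k, fixture_citation_body(k))
    })
    write_text(file.path(dir, "citations.bib"), qz_format_bibtex(entries))
  }
  write_text(file.path(dir, "action", "action.yaml"),
             fixture_action_yaml(node, uuids))
}

#' Generate one synthetic artifact from a fixture specification
#'
#' Writes the focal (last) chain node as a `.qza`/`.qzv` archive embedding
#' every earlier node in its provenance tree, and returns the ground-truth
#' record of what was generated. Deterministic: the same spec and seed yield
#' a byte-identical archive.
#'
#' @param spec A [qz_fixture_spec()].
#' @param out_path Destination archive path.
#' @param framework_version Framework version string recorded in VERSION.
#' @return A `qz_fixture_record`: `path`, `focal_uuid`, `uuids` (chain
#'   order), `ancestor_uuids`, `adjacency` (data.frame `from`, `to`,
#'   `param`), `citations` (named list uuid -> keys), `payload_md5` (named by
#'   `data/`-relative path), `semantic_type`, `data_format`, `kind`,
#'   `archive_version`.
#' @export
qz_generate_fixture <- function(spec, out_path,
                                framework_version = "2020.8.0") {
  generate_fixture_impl(spec, out_path, framework_version)
}

# tamper_tree(root_dir) runs after the checksum manifest is written (so
# corruption is visible to verification); tamper_stage(stage_dir) runs last,
# before zipping, and can add extra top-level roots.
generate_fixture_impl <- function(spec, out_path,
                                  framework_version = "2020.8.0",
                                  tamper_tree = NULL, tamper_stage = NULL) {
  stopifnot(inherits(spec, "qz_fixture_spec"))
  n <- length(spec$nodes)
  uuids <- with_preserved_seed(spec$seed,
                               vapply(seq_len(n), function(i) random_uuid4(), ""))
  focal <- spec$nodes[[n]]
  focal_uuid <- uuids[[n]]

  stage <- tempfile("qz-fixture-")
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  root <- file.path(stage, focal_uuid)
  dir.create(root, recursive = TRUE)

  write_text(file.path(root, "VERSION"),
             version_text(framework_version, spec$archive_version))
  write_text(file.path(root, "metadata.yaml"),
             metadata_text(focal_uuid, focal$semantic_type, focal$data_format))

  payload_md5 <- character()
  for (name in names(focal$payloads)) {
    bytes <- payload_bytes(name, focal$payloads[[name]])
    dest <- file.path(root, "data", name)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    writeBin(bytes, dest)
    payload_md5[[name]] <- md5_raw(bytes)
  }

  write_node_tree(file.path(root, "provenance"), focal, focal_uuid, uuids,
                  framework_version)
  for (i in seq_len(n - 1L)) {
    write_node_tree(file.path(root, "provenance", "artifacts", uuids[[i]]),
                    spec$nodes[[i]], uuids[[i]], uuids, framework_version)
  }
  if (spec$archive_version >= 5L) write_checksum_manifest(root)
  if (!is.null(tamper_tree)) tamper_tree(root)
  if (!is.null(tamper_stage)) tamper_stage(stage)
  zq_write_archive(stage, out_path, fixed_mtime = FIXTURE_MTIME)

  adjacency <- data.frame(from = character(), to = character(),
                          param = character(), stringsAsFactors = FALSE)
  citations <- list()
  for (i in seq_len(n)) {
    node <- spec$nodes[[i]]
    if (length(node$inputs)) {
      adjacency <- rbind(adjacency, data.frame(
        from = unname(uuids[node$inputs]), to = uuids[[i]],
        param = names(node$inputs), stringsAsFactors = FALSE))
    }
    citations[[uuids[[i]]]] <- node$citations
  }
  structure(
    list(path = out_path, focal_uuid = focal_uuid, uuids = uuids,
         ancestor_uuids = uuids[-n], adjacency = adjacency,
         citations = citations, payload_md5 = payload_md5,
         semantic_type = focal$semantic_type,
         data_format = focal$data_format,
         kind = if (identical(focal$semantic_type, "Visualization"))
           "visualization" else "regular",
         archive_version = spec$archive_version),
    class = "qz_fixture_record"
  )
}

fixture_fasta <- function() {
  paste0(">asv1 synthetic\nACGTACGTACGTAGCTAGCTAGGATCCA\n",
         ">asv2 synthetic\nTTGACGGCTAGCTAGATCGATCGATTGA\n")
}

fixture_fastq <- function(tag) {
  paste0("@read1/", tag, "\nACGTACGTACGT\n+\nIIIIIIIIIIII\n",
         "@read2/", tag, "\nTTGCAGTCAGTC\n+\nIIIIIIIIIIII\n")
}

fixture_taxonomy_tsv <- function() {
  paste0("Feature ID\tTaxon\tConfidence\n",
         "asv1\tk__Bacteria; p__Firmicutes\t0.99\n",
         "asv2\tk__Bacteria; p__Bacteroidota\t0.97\n")
}

#' Generate the canonical suite of test fixtures
#'
#' Writes ten artifacts into `dir`: six well-formed (import-only, single-file
#' FASTA, multi-file gzipped FASTQ, a three-node linear chain, a
#' diamond-shaped ancestry, and a visualization) and four corrupt variants
#' (two root directories, root/metadata uuid mismatch, one flipped payload
#' byte, truncated VERSION). Each record carries the generation-time ground
#' truth; corrupt records carry `corrupt`, the expected error condition class
#' (or `"checksum-mismatch"` for the flipped byte, which loads fine but fails
#' verification).
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed; per-fixture seeds are derived from it.
#' @return Named list of 10 `qz_fixture_record`s.
#' @export
qz_standard_suite <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  sub_seed <- function(k) (seed * 131L + k) %% 2147483L + k

  import_node <- function(type = "SampleData[SequencesWithQuality]",
                          format = "SingleLanePerSampleSingleEndFastqDirFmt",
                          payloads = list(), citations = c("framework|qiime2:2020.8.0")) {
    qz_fixture_node(type, format, payloads = payloads,
                    action_kind = "import", citations = citations)
  }

  recs <- list()

  recs$import_only <- qz_generate_fixture(
    qz_fixture_spec(list(import_node(
      payloads = list("sequences.fastq.gz" = fixture_fastq("s1")))),
      seed = sub_seed(1L)),
    file.path(dir, "import-only.qza"))

  recs$single_file <- qz_generate_fixture(
    qz_fixture_spec(list(qz_fixture_node(
      "FeatureData[Sequence]", "DNASequencesDirectoryFormat",
      payloads = list("dna-sequences.fasta" = fixture_fasta()),
      action_kind = "import",
      citations = c("framework|qiime2:2020.8.0"))),
      seed = sub_seed(2L)),
    file.path(dir, "rep-seqs.qza"))

  recs$multi_file <- qz_generate_fixture(
    qz_fixture_spec(list(qz_fixture_node(
      "SampleData[PairedEndSequencesWithQuality]",
      "CasavaOneEightSingleLanePerSampleDirFmt",
      payloads = list(
        "sampleA_L001_R1_001.fastq.gz" = fixture_fastq("A1"),
        "sampleA_L001_R2_001.fastq.gz" = fixture_fastq("A2"),
        "sampleB_L001_R1_001.fastq.gz" = fixture_fastq("B1"),
        "sampleB_L001_R2_001.fastq.gz" = fixture_fastq("B2")),
      action_kind = "import",
      citations = c("framework|qiime2:2020.8.0"))),
      seed = sub_seed(3L)),
    file.path(dir, "demux.qza"))

  chain_spec <- qz_fixture_spec(list(
    import_node(citations = c("framework|qiime2:2020.8.0", "cutadapt2011")),
    qz_fixture_node("FeatureData[Sequence]", "DNASequencesDirectoryFormat",
                    action_kind = "method", plugin = "dada2",
                    action = "denoise-single",
                    inputs = c(demultiplexed_seqs = 1L),
                    parameters = c(trunc_len = "240"),
                    citations = c("framework|qiime2:2020.8.0", "dada2-2016")),
    qz_fixture_node("FeatureData[Taxonomy]", "TSVTaxonomyDirectoryFormat",
                    payloads = list("taxonomy.tsv" = fixture_taxonomy_tsv()),
                    action_kind = "method", plugin = "feature-classifier",
                    action = "classify-sklearn",
                    inputs = c(reads = 2L),
                    citations = c("framework|qiime2:2020.8.0",
                                  "sklearn-2011"))),
    seed = sub_seed(4L))
  recs$chain <- qz_generate_fixture(chain_spec, file.path(dir, "taxonomy.qza"))

  diamond_spec <- qz_fixture_spec(list(
    import_node(citations = c("framework|qiime2:2020.8.0")),
    qz_fixture_node("FeatureTable[Frequency]", "BIOMV210DirFmt",
                    action_kind = "method", plugin = "dada2",
                    action = "denoise-single",
                    inputs = c(demultiplexed_seqs = 1L),
                    citations = c("dada2-2016")),
    qz_fixture_node("Phylogeny[Rooted]", "NewickDirectoryFormat",
                    action_kind = "pipeline", plugin = "phylogeny",
                    action = "align-to-tree-mafft-fasttree",
                    inputs = c(sequences = 1L),
                    citations = c("mafft2013", "fasttree2010")),
    qz_fixture_node("SampleData[AlphaDiversity]", "AlphaDiversityDirectoryFormat",
                    payloads = list("alpha-diversity.tsv" = "sample\tfaith_pd\nA\t3.1\nB\t2.7\n"),
                    action_kind = "pipeline", plugin = "diversity",
                    action = "core-metrics-phylogenetic",
                    inputs = c(table = 2L, phylogeny = 3L),
                    citations = c("framework|qiime2:2020.8.0",
                                  "faith1992"))),
    seed = sub_seed(5L))
  recs$diamond <- qz_generate_fixture(diamond_spec,
                                      file.path(dir, "core-metrics.qza"))

  recs$visualization <- qz_generate_fixture(
    qz_fixture_spec(list(qz_fixture_node(
      "Visualization", NULL,
      payloads = list(
        "index.html" = "<html><body><h1>Synthetic report</h1></body></html>\n",
        "css/style.css" = "body { font-family: sans-serif; }\n"),
      action_kind = "visualizer", plugin = "demux", action = "summarize",
      citations = c("framework|qiime2:2020.8.0"))),
      seed = sub_seed(6L)),
    file.path(dir, "summary.qzv"))

  # -- corrupt variants ------------------------------------------------------
  base_spec <- function(k) qz_fixture_spec(list(qz_fixture_node(
    "FeatureData[Sequence]", "DNASequencesDirectoryFormat",
    payloads = list("dna-sequences.fasta" = fixture_fasta()),
    action_kind = "import", citations = c("framework|qiime2:2020.8.0"))),
    seed = sub_seed(k))

  recs$corrupt_dual_root <- generate_fixture_impl(
    base_spec(7L), file.path(dir, "corrupt-dual-root.qza"),
    tamper_stage = function(stage) {
      extra <- file.path(stage, "not-a-uuid-second-root")
      dir.create(extra)
      write_text(file.path(extra, "stray.txt"), "stray\n")
    })
  recs$corrupt_dual_root$corrupt <- "qz_malformed_error"

  recs$corrupt_uuid_mismatch <- generate_fixture_impl(
    base_spec(8L), file.path(dir, "corrupt-uuid-mismatch.qza"),
    tamper_tree = function(root) {
      write_text(file.path(root, "metadata.yaml"),
                 metadata_text("00000000-0000-4000-8000-000000000bad",
                               "FeatureData[Sequence]",
                               "DNASequencesDirectoryFormat"))
    })
  recs$corrupt_uuid_mismatch$corrupt <- "qz_integrity_error"

  recs$corrupt_checksum <- generate_fixture_impl(
    base_spec(9L), file.path(dir, "corrupt-checksum.qza"),
    tamper_tree = function(root) {
      f <- file.path(root, "data", "dna-sequences.fasta")
      bytes <- readBin(f, "raw", file.size(f))
      bytes[length(bytes) - 1L] <- xor(bytes[length(bytes) - 1L], as.raw(0x01))
      writeBin(bytes, f)
    })
  recs$corrupt_checksum$corrupt <- "checksum-mismatch"
  recs$corrupt_checksum$tampered_member <- "data/dna-sequences.fasta"

  recs$corrupt_version <- generate_fixture_impl(
    base_spec(10L), file.path(dir, "corrupt-version.qza"),
    tamper_tree = function(root) {
      write_text(file.path(root, "VERSION"), "QIIME 2\n")
    })
  recs$corrupt_version$corrupt <- "qz_version_error"

  recs
}
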