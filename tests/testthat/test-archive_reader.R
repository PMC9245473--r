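test_that("qz_read_version parses well-formed and rejects garbled VERSION text", {
  v <- qz_read_version("QIIME 2\narchive: 5\nframework: 2020.8.0\n")
  expect_s3_class(v, "qz_version")
  expect_identical(v$framework_name, "QIIME 2")
  expect_identical(v$archive_version, 5L)
  expect_identical(v$framework_version, "2020.8.0")

  expect_identical(
    qz_read_version("QIIME 2\narchive: 4\nframework: 2019.10.0\n")$archive_version,
    4L)

  err <- expect_error(
    qz_read_version("QIIME 2\narchive: five\nframework: 2020.8.0\n"),
    class = "qz_version_error")
  expect_match(conditionMessage(err), "five")
  expect_error(qz_read_version("QIIME 2\n"), class = "qz_version_error")
  expect_error(qz_read_version("QIIME 2\narchive: 5\nfr@mework 2020\n"),
               class = "qz_version_error")
  expect_error(qz_read_version("QIIME 2\narchive: 0\nframework: x\n"),
               class = "qz_version_error")
})

test_that("qz_read_metadata parses the (uuid, type, format) triple", {
  m <- qz_read_metadata(paste0(
    "uuid: 5e2d1c3a-0000-4000-8000-0000000000aa\n",
    "type: FeatureData[Sequence]\n",
    "format: DNASequencesDirectoryFormat\n"))
  expect_identical(m$uuid, "5e2d1c3a-0000-4000-8000-0000000000aa")
  expect_identical(m$semantic_type, "FeatureData[Sequence]")
  expect_identical(m$data_format, "DNASequencesDirectoryFormat")

  viz <- qz_read_metadata(paste0(
    "uuid: 5e2d1c3a-0000-4000-8000-0000000000aa\n",
    "type: Visualization\nformat: null\n"))
  expect_true(is.na(viz$data_format))

  # uppercase uuid accepted syntactically, canonicalized to lowercase
  up <- qz_read_metadata(paste0(
    "uuid: 5E2D1C3A-0000-4000-8000-0000000000AA\n",
    "type: Visualization\nformat: null\n"))
  expect_identical(up$uuid, "5e2d1c3a-0000-4000-8000-0000000000aa")

  err <- expect_error(
    qz_read_metadata("uuid: 5e2d1c3a-0000-4000-8000-0000000000aa\nformat: null\n"),
    class = "qz_metadata_error")
  expect_match(conditionMessage(err), "type")
  expect_error(
    qz_read_metadata("uuid: not-a-uuid\ntype: X\nformat: null\n"),
    class = "qz_validation_error")
})

test_that("qz_detect_root enforces the single-UUID-root rule", {
  recs <- qz_test_suite()
  for (nm in GOOD_FIXTURES) {
    expect_identical(qz_detect_root(recs[[nm]]$path), recs[[nm]]$focal_uuid,
                     info = nm)
  }
  expect_error(qz_detect_root(recs$corrupt_dual_root$path),
               class = "qz_malformed_error")

  txt <- tempfile(fileext = ".qza")
  writeLines("this is not a zip archive", txt)
  expect_error(qz_detect_root(txt), class = "qz_format_error")
  expect_error(qz_detect_root(tempfile("no-such-file-")),
               class = "qz_format_error")

  bad_root <- raw_artifact(
    list("not-a-uuid/VERSION" = simple_version_text()),
    tempfile(fileext = ".qza"))
  expect_error(qz_detect_root(bad_root), class = "qz_malformed_error")

  top_file <- raw_artifact(
    list("VERSION" = simple_version_text()),
    tempfile(fileext = ".qza"))
  expect_error(qz_detect_root(top_file), class = "qz_malformed_error")
})

test_that("qz_load_artifact round-trips every generation-time property", {
  recs <- qz_test_suite()
  for (nm in GOOD_FIXTURES) {
    r <- recs[[nm]]
    a <- qz_load_artifact(r$path)
    expect_identical(a$metadata$uuid, r$focal_uuid, info = nm)
    expect_identical(a$metadata$semantic_type, r$semantic_type, info = nm)
    if (is.null(r$data_format)) {
      expect_true(is.na(a$metadata$data_format), info = nm)
    } else {
      expect_identical(a$metadata$data_format, r$data_format, info = nm)
    }
    expect_identical(a$version$archive_version, r$archive_version, info = nm)
    expect_identical(a$kind, r$kind, info = nm)
    expect_identical(a$data_entries,
                     sort(names(r$payload_md5), method = "radix"), info = nm)
    expect_identical(a$n_ancestors, length(r$ancestor_uuids), info = nm)
    expect_true(a$has_provenance, info = nm)
    # idempotence: loading twice yields identical values
    expect_identical(a, qz_load_artifact(r$path), info = nm)
  }
  expect_error(qz_load_artifact(recs$corrupt_uuid_mismatch$path),
               class = "qz_integrity_error")
  expect_error(qz_load_artifact(recs$corrupt_version$path),
               class = "qz_version_error")
})

test_that("qz_verify_checksums matches an independent md5 oracle", {
  recs <- qz_test_suite()
  for (nm in GOOD_FIXTURES) {
    expect_identical(nrow(qz_verify_checksums(recs[[nm]]$path)), 0L, info = nm)
  }

  r <- recs$corrupt_checksum
  mm <- qz_verify_checksums(r$path)
  expect_identical(nrow(mm), 1L)
  expect_identical(mm$path, r$tampered_member)
  # the observed digest must agree with tools::md5sum on the same member
  expect_identical(
    mm$observed,
    oracle_member_md5(r$path, paste0(r$focal_uuid, "/", r$tampered_member)))
  expect_false(mm$expected == mm$observed)
})

test_that("empty payloads carry the canonical empty-input md5 in the manifest", {
  # oracle: tools::md5sum of a zero-byte file
  empty <- tempfile()
  file.create(empty)
  oracle <- unname(tools::md5sum(empty))
  expect_identical(oracle, "d41d8cd98f00b204e9800998ecf8427e")

  spec <- qz_fixture_spec(list(qz_fixture_node(
    "FeatureData[Sequence]", "DNASequencesDirectoryFormat",
    payloads = list("empty.txt" = ""), action_kind = "import")), seed = 5L)
  rec <- qz_generate_fixture(spec, tempfile(fileext = ".qza"))
  a <- qz_load_artifact(rec$path)
  expect_identical(unname(a$checksum_manifest[["data/empty.txt"]]), oracle)
  expect_identical(nrow(qz_verify_checksums(a)), 0L)
})

test_that("pre-manifest archive versions degrade gracefully", {
  spec <- qz_fixture_spec(list(qz_fixture_node(
    "FeatureData[Sequence]", "DNASequencesDirectoryFormat",
    payloads = list("x.fasta" = ">a\nACGT\n"), action_kind = "import")),
    seed = 11L, archive_version = 4L)
  rec <- qz_generate_fixture(spec, tempfile(fileext = ".qza"))
  a <- qz_load_artifact(rec$path)
  expect_null(a$checksum_manifest)
  # absent manifest is an unsupported-operation signal, not a failure list
  expect_error(qz_verify_checksums(a),
               class = "qz_checksum_unsupported_error")
})

test_that("metadata semantic type wins over file extension for kind", {
  # a Visualization stored under .qza: metadata is authoritative, with warning
  spec <- qz_fixture_spec(list(qz_fixture_node(
    "Visualization", NULL, payloads = list("index.html" = "<html></html>\n"),
    action_kind = "visualizer")), seed = 12L)
  rec <- qz_generate_fixture(spec, tempfile(fileext = ".qza"))
  a <- qz_load_artifact(rec$path)
  expect_identical(a$kind, "visualization")
  expect_true(any(grepl("disagrees", a$warnings)))
})
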