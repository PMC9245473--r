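# Creating visualization artifacts from static HTML directories.
#
# This is the one writing operation: any directory with an index.html at its
# top level becomes a structurally valid .qzv — a single compressed file that
# travels a multi-page report (HTML, CSS, scripts, images) through pipelines
# that never touch Qiime2. The archive gets a fresh version-4 UUID, archive
# format version 5 (the newest dialect, with a checksum manifest), minimal
# honest provenance (an import-kind action naming the source directory), and
# the toolkit's own citation.

ARCHIVE_VERSION <- 5L

random_uuid4 <- function() {
  b <- sample.int(256L, 16L, replace = TRUE) - 1L
  b[7L] <- bitwOr(bitwAnd(b[7L], 0x0fL), 0x40L)  # version nibble = 4
  b[9L] <- bitwOr(bitwAnd(b[9L], 0x3fL), 0x80L)  # variant = 10xx
  h <- paste(sprintf("%02x", b), collapse = "")
  paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
        substr(h, 17, 20), substr(h, 21, 32), sep = "-")
}

version_text <- function(framework_version, archive_version = ARCHIVE_VERSION) {
  sprintf("QIIME 2\narchive: %d\nframework: %s\n", archive_version,
          framework_version)
}

metadata_text <- function(uuid, type, format) {
  sprintf("uuid: %s\ntype: %s\nformat: %s\n", uuid, type,
          if (is.null(format) || is.na(format)) "null" else format)
}

write_text <- function(path, text) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")  # binary: exact bytes, no CRLF translation
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
}

# md5sum-format manifest over every file under `root` except the manifest
# itself; root-relative "/" paths in lexicographic order.
write_checksum_manifest <- function(root) {
  rel <- lex_sort(list.files(root, recursive = TRUE, all.files = TRUE,
                             no.. = TRUE))
  rel <- setdiff(rel, "checksums.md5")
  lines <- vapply(rel, function(p) {
    sprintf("%s  %s", md5_file(file.path(root, p)), p)
  }, "")
  write_text(file.path(root, "checksums.md5"),
             paste0(paste(lines, collapse = "\n"), "\n"))
}

#' The toolkit's own citation entry
#'
#' A stable, syntactically valid BibTeX record written into the provenance
#' tree of every artifact this package creates, so `cite`-style aggregation
#' over downstream artifacts credits the generating tool.
#'
#' @return A `qz_citation` of kind `misc` with key `qzkit-toolkit`.
#' @export
qz_self_citation <- function() {
  qz_citation("misc", "qzkit-toolkit", paste0(
    "\n  title = {qzkit: a standalone toolkit for {QIIME 2} artifact archives},",
    "\n  howpublished = {R package},",
    "\n  year = {2026}\n"))
}

#' Package an HTML directory as a visualization artifact (.qzv)
#'
#' Builds a structurally valid visualization artifact from a directory of
#' static HTML: semantic type `Visualization`, null data format, archive
#' version 5, the directory tree mirrored under `data/`, an import-kind
#' provenance action recording the source directory (and optional note), the
#' toolkit self-citation, and a complete md5 checksum manifest. The archive
#' is written atomically (temp file + rename), so a failure never leaves a
#' half-written artifact behind.
#'
#' @param html_dir Directory containing `index.html` at its top level.
#' @param output_path Destination path; a warning is emitted (but the build
#'   proceeds) when it does not end in `.qzv`.
#' @param framework_version Text recorded as the framework version.
#' @param note Optional free-text note recorded as an action parameter.
#' @param include_hidden Include dot-prefixed files from `html_dir`.
#' @return The `qz_artifact` obtained by re-loading the written archive; it
#'   passes [qz_verify_checksums()] with zero mismatches.
#' @examples
#' \dontrun{qz_make_visualization("report/", "report.qzv")}
#' @export
qz_make_visualization <- function(html_dir, output_path,
                                  framework_version = paste0(
                                    "qzkit-", utils::packageVersion("qzkit")),
                                  note = NULL, include_hidden = FALSE) {
  if (!dir.exists(html_dir)) {
    qz_error("qz_precondition_error",
             sprintf("input directory does not exist: %s", html_dir))
  }
  if (!file.exists(file.path(html_dir, "index.html"))) {
    qz_error("qz_precondition_error",
             sprintf("'%s' must contain an index.html at its top level (viewers open data/index.html)",
                     html_dir))
  }
  if (!grepl("\\.qzv$", output_path)) {
    warning(sprintf("output path '%s' does not end in .qzv", output_path),
            call. = FALSE)
  }
  rel <- list.files(html_dir, recursive = TRUE, all.files = include_hidden,
                    no.. = TRUE)
  if (!include_hidden) rel <- rel[!grepl("(^|/)\\.", rel)]
  unreadable <- rel[file.access(file.path(html_dir, rel), 4L) != 0L]
  if (length(unreadable) > 0L) {
    qz_error("qz_precondition_error",
             sprintf("unreadable file(s) under %s: %s", html_dir,
                     paste(unreadable, collapse = ", ")))
  }

  uuid <- random_uuid4()
  stage <- tempfile("qzv-stage-")
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  root <- file.path(stage, uuid)

  for (p in rel) {
    dest <- file.path(root, "data", p)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    if (!file.copy(file.path(html_dir, p), dest)) {
      qz_error("qz_precondition_error",
               sprintf("cannot copy '%s' from %s", p, html_dir))
    }
  }
  vtxt <- version_text(framework_version)
  mtxt <- metadata_text(uuid, "Visualization", NULL)
  write_text(file.path(root, "VERSION"), vtxt)
  write_text(file.path(root, "metadata.yaml"), mtxt)
  write_text(file.path(root, "provenance", "VERSION"), vtxt)
  write_text(file.path(root, "provenance", "metadata.yaml"), mtxt)
  write_text(file.path(root, "provenance", "citations.bib"),
             qz_format_bibtex(list(qz_self_citation())))
  params <- list(list(source_directory = basename(normalizePath(html_dir))))
  if (!is.null(note)) params <- c(params, list(list(note = note)))
  write_text(file.path(root, "provenance", "action", "action.yaml"),
             yaml::as.yaml(list(action = list(type = "import",
                                              parameters = params))))
  write_checksum_manifest(root)
  zq_write_archive(stage, output_path)
  qz_load_artifact(output_path)
}
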