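# Reading and validating artifact archives.
#
# An artifact is a ZIP archive with exactly one top-level directory named by
# the artifact's UUID. The root holds:
#   VERSION         3-line banner / "archive: N" / "framework: V"
#   metadata.yaml   flat mapping: uuid, type (semantic type), format
#   checksums.md5   md5sum-style manifest (archive version >= 5)
#   data/           the payload files
#   provenance/     optional embedded ancestry tree

UUID_REGEX <- paste0("^[0-9a-fA-F]{8}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-",
                     "[0-9a-fA-F]{4}-[0-9a-fA-F]{12}$")

is_uuid <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(UUID_REGEX, x)
}

#' Detect the UUID-named root directory of an artifact archive
#'
#' Every well-formed artifact places all its members under a single top-level
#' directory whose name is the artifact UUID. Archives with zero or several
#' top-level entries, top-level files, unsafe member paths (absolute or
#' containing `..`), or a non-UUID root name are rejected.
#'
#' @param path Path to a `.qza`/`.qzv` file.
#' @return The root directory name: a lowercase hyphenated UUID string.
#' @examples
#' \dontrun{qz_detect_root("table.qza")}
#' @export
qz_detect_root <- function(path) {
  members <- zq_members(path)
  if (length(members) == 0L) {
    qz_error("qz_malformed_error", sprintf("'%s' is an empty archive", path),
             path = path)
  }
  if (any(grepl("^/", members)) || any(grepl("(^|/)\\.\\.(/|$)", members))) {
    qz_error("qz_malformed_error",
             sprintf("'%s' contains unsafe member paths", path), path = path)
  }
  plain <- sub("/$", "", members)
  top_files <- members[!grepl("/", plain)]
  top_files <- top_files[!grepl("/$", top_files)]
  if (length(top_files) > 0L) {
    qz_error("qz_malformed_error",
             sprintf("'%s' has top-level files outside a root directory: %s",
                     path, paste(top_files, collapse = ", ")),
             path = path)
  }
  roots <- unique(sub("/.*$", "", members))
  if (length(roots) != 1L) {
    qz_error("qz_malformed_error",
             sprintf("'%s' has %d top-level directories (expected exactly 1): %s",
                     path, length(roots), paste(lex_sort(roots), collapse = ", ")),
             path = path, roots = roots)
  }
  if (!is_uuid(roots)) {
    qz_error("qz_malformed_error",
             sprintf("root directory of '%s' is not a UUID: %s", path, roots),
             path = path, root = roots)
  }
  tolower(roots)
}

#' Parse the VERSION member of an artifact
#'
#' The VERSION file has three non-empty lines: a framework banner
#' (`QIIME 2`), `archive: N` with the integer archive format version, and
#' `framework: V` with the framework release string. Artifacts written by
#' different framework releases are not mutually compatible, so both versions
#' are surfaced rather than hidden.
#'
#' @param text Contents of the VERSION member.
#' @return A `qz_version` object with fields `framework_name`,
#'   `archive_version` (integer) and `framework_version`.
#' @export
qz_read_version <- function(text) {
  ln <- trimws(strsplit(text, "\r?\n")[[1L]])
  ln <- ln[nzchar(ln)]
  if (length(ln) < 3L) {
    qz_error("qz_version_error",
             sprintf("VERSION is truncated: expected 3 non-empty lines, got %d",
                     length(ln)),
             lines = ln)
  }
  banner <- ln[1L]
  m <- regmatches(ln[2L], regexec("^archive:[ \t]*(.+)$", ln[2L]))[[1L]]
  if (length(m) != 2L) {
    qz_error("qz_version_error",
             sprintf("cannot parse archive version line: '%s'", ln[2L]),
             line = ln[2L])
  }
  if (!grepl("^[0-9]+$", m[2L])) {
    qz_error("qz_version_error",
             sprintf("archive version is not an integer: '%s'", ln[2L]),
             line = ln[2L])
  }
  av <- as.integer(m[2L])
  if (is.na(av) || av < 1L) {
    qz_error("qz_version_error",
             sprintf("archive version must be >= 1: '%s'", ln[2L]),
             line = ln[2L])
  }
  f <- regmatches(ln[3L], regexec("^framework:[ \t]*(.+)$", ln[3L]))[[1L]]
  if (length(f) != 2L || !nzchar(trimws(f[2L]))) {
    qz_error("qz_version_error",
             sprintf("cannot parse framework version line: '%s'", ln[3L]),
             line = ln[3L])
  }
  structure(
    list(framework_name = banner, archive_version = av,
         framework_version = trimws(f[2L])),
    class = "qz_version"
  )
}

#' Parse the metadata.yaml member of an artifact
#'
#' The two attributes that define an artifact's payload are its semantic
#' `type` (e.g. `FeatureData[Sequence]`, `Visualization`) and its data
#' `format` (the on-disk payload layout). Visualizations record a literal
#' `null` format, which maps here to `NA`.
#'
#' @param text Contents of the metadata.yaml member (a flat YAML mapping with
#'   keys `uuid`, `type`, `format`).
#' @return A `qz_metadata` object with fields `uuid` (canonical lowercase),
#'   `semantic_type`, and `data_format` (`NA_character_` when null).
#' @export
qz_read_metadata <- function(text) {
  y <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      qz_error("qz_metadata_error",
               sprintf("cannot parse metadata.yaml: %s", conditionMessage(e)))
    }
  )
  if (!is.list(y)) {
    qz_error("qz_metadata_error", "metadata.yaml is not a YAML mapping")
  }
  for (k in c("uuid", "type", "format")) {
    if (!(k %in% names(y))) {
      qz_error("qz_metadata_error",
               sprintf("metadata.yaml is missing required key '%s'", k),
               key = k)
    }
  }
  uuid <- as.character(y$uuid)
  if (!is_uuid(uuid)) {
    qz_error("qz_validation_error",
             sprintf("metadata uuid is not a valid UUID: '%s'", uuid),
             uuid = uuid)
  }
  type <- as.character(y$type)
  if (length(type) != 1L || !nzchar(type)) {
    qz_error("qz_metadata_error", "metadata 'type' must be a non-empty string")
  }
  fmt <- y$format
  fmt <- if (is.null(fmt)) NA_character_ else as.character(fmt)
  structure(
    list(uuid = tolower(uuid), semantic_type = type, data_format = fmt),
    class = "qz_metadata"
  )
}

parse_checksum_manifest <- function(text, path) {
  ln <- strsplit(text, "\r?\n")[[1L]]
  ln <- ln[nzchar(trimws(ln))]
  m <- regmatches(ln, regexec("^([0-9a-fA-F]{32})[ \t][ *](.+)$", ln))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    qz_error("qz_malformed_error",
             sprintf("cannot parse checksums.md5 line in '%s': '%s'",
                     path, ln[bad][1L]),
             line = ln[bad][1L])
  }
  digests <- tolower(vapply(m, `[[`, "", 2L))
  names(digests) <- vapply(m, `[[`, "", 3L)
  digests
}

#' Load an artifact archive
#'
#' Opens a `.qza`/`.qzv` file, validates its structure, and returns its
#' metadata, format versions, payload listing, provenance flag, and (for
#' archive version >= 5) the md5 checksum manifest. Loading is side-effect
#' free so callers can batch over many artifacts; only the ZIP central
#' directory and the three small metadata members are read — payload bytes
#' are never touched.
#'
#' @param path Path to a `.qza`/`.qzv` file.
#' @return A `qz_artifact` object: `source_path`, `kind` (`"regular"` or
#'   `"visualization"`), `metadata` ([qz_read_metadata()]), `version`
#'   ([qz_read_version()]), `data_entries` (payload paths relative to `data/`,
#'   lexicographic order), `has_provenance`, `n_ancestors`,
#'   `checksum_manifest` (named character or `NULL`), `warnings`.
#' @examples
#' \dontrun{
#' a <- qz_load_artifact("rep-seqs.qza")
#' a$metadata$semantic_type
#' }
#' @export
qz_load_artifact <- function(path) {
  root <- qz_detect_root(path)
  members <- zq_members(path)

  for (req in c("VERSION", "metadata.yaml")) {
    if (!zq_has_member(members, paste0(root, "/", req))) {
      qz_error("qz_malformed_error",
               sprintf("'%s' is missing required member %s", path, req),
               path = path, member = req)
    }
  }
  version <- qz_read_version(zq_read_text(path, paste0(root, "/VERSION")))
  if (version$archive_version < 2L) {
    qz_error("qz_version_error",
             sprintf("unsupported archive version %d (expected >= 2)",
                     version$archive_version),
             archive_version = version$archive_version)
  }
  meta <- qz_read_metadata(zq_read_text(path, paste0(root, "/metadata.yaml")))
  if (!identical(meta$uuid, root)) {
    qz_error("qz_integrity_error",
             sprintf("root directory '%s' does not match metadata uuid '%s'",
                     root, meta$uuid),
             root = root, uuid = meta$uuid)
  }

  data_prefix <- paste0(root, "/data/")
  under_data <- members[startsWith(members, data_prefix) &
                          !grepl("/$", members)]
  data_entries <- lex_sort(substring(under_data, nchar(data_prefix) + 1L))
  if (length(data_entries) == 0L) {
    qz_error("qz_malformed_error",
             sprintf("'%s' carries no data/ payload files", path), path = path)
  }

  prov_prefix <- paste0(root, "/provenance/")
  has_provenance <- any(startsWith(members, prov_prefix))
  anc_prefix <- paste0(prov_prefix, "artifacts/")
  under_anc <- members[startsWith(members, anc_prefix)]
  anc_ids <- unique(sub("/.*$", "", substring(under_anc, nchar(anc_prefix) + 1L)))
  anc_ids <- anc_ids[nzchar(anc_ids)]

  manifest <- NULL
  cks_member <- paste0(root, "/checksums.md5")
  if (zq_has_member(members, cks_member)) {
    manifest <- parse_checksum_manifest(zq_read_text(path, cks_member), path)
  } else if (version$archive_version >= 5L) {
    qz_error("qz_malformed_error",
             sprintf("'%s' (archive version %d) is missing checksums.md5",
                     path, version$archive_version),
             path = path)
  }

  warnings <- character()
  ext <- tolower(tools::file_ext(path))
  is_viz <- identical(meta$semantic_type, "Visualization")
  kind <- if (is_viz) "visualization" else "regular"
  if ((is_viz && ext == "qza") || (!is_viz && ext == "qzv")) {
    warnings <- c(warnings, sprintf(
      "file extension '.%s' disagrees with semantic type '%s'; metadata wins",
      ext, meta$semantic_type))
  }

  structure(
    list(source_path = normalizePath(path), kind = kind, metadata = meta,
         version = version, data_entries = data_entries,
         has_provenance = has_provenance, n_ancestors = length(anc_ids),
         checksum_manifest = manifest, warnings = warnings),
    class = "qz_artifact"
  )
}

#' Verify the md5 checksum manifest of an artifact
#'
#' Recomputes the md5 digest of every member listed in `checksums.md5`
#' (the manifest itself is never listed) and reports mismatches. An absent
#' manifest (archives older than version 5) raises a
#' `qz_checksum_unsupported_error`, distinguishable from a verification
#' failure.
#'
#' @param artifact A `qz_artifact` or a path to one.
#' @return A data.frame with columns `path`, `expected`, `observed`; zero rows
#'   means every manifested member verified.
#' @export
qz_verify_checksums <- function(artifact) {
  if (is.character(artifact)) artifact <- qz_load_artifact(artifact)
  stopifnot(inherits(artifact, "qz_artifact"))
  man <- artifact$checksum_manifest
  if (is.null(man)) {
    qz_error("qz_checksum_unsupported_error",
             "artifact has no checksums.md5 manifest; verification unsupported")
  }
  root <- artifact$metadata$uuid
  rel <- setdiff(names(man), "checksums.md5")
  observed <- vapply(rel, function(p) {
    md5_raw(zq_read_raw(artifact$source_path, paste0(root, "/", p)))
  }, "")
  bad <- observed != unname(man[rel])
  data.frame(path = rel[bad], expected = unname(man[rel][bad]),
             observed = observed[bad], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.qz_artifact <- function(x, ...) {
  cat(sprintf("<qz_artifact> %s\n", basename(x$source_path)))
  cat(sprintf("  uuid:    %s\n", x$metadata$uuid))
  cat(sprintf("  kind:    %s\n", x$kind))
  cat(sprintf("  type:    %s\n", x$metadata$semantic_type))
  cat(sprintf("  format:  %s\n",
              if (is.na(x$metadata$data_format)) "-" else x$metadata$data_format))
  cat(sprintf("  archive: %d (framework %s)\n", x$version$archive_version,
              x$version$framework_version))
  cat(sprintf("  data:    %d file(s); provenance: %s (%d ancestor(s))\n",
              length(x$data_entries),
              if (x$has_provenance) "yes" else "no", x$n_ancestors))
  for (w in x$warnings) cat(sprintf("  warning: %s\n", w))
  invisible(x)
}
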