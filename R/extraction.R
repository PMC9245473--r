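# Extracting payloads and streaming text members.
#
# The extraction convention: an artifact with a single data file is written
# directly into the output directory renamed after the artifact file itself
# (rep-seqs.qza containing data/dna-sequences.fasta -> rep-seqs.fasta, the
# payload's compound extension preserved whole). Artifacts with several data
# files, and every visualization, get their own directory named after the
# artifact, preserving the data/-relative subtree. This lets many artifacts
# be extracted at once into one flat, readably named output directory.

artifact_base <- function(path) sub("\\.[^.]*$", "", basename(path))

# Compound extension: everything from the first dot of the payload basename
# (".fastq.gz", ".fasta", ...); empty when the payload has no dot.
payload_ext <- function(entry) sub("^[^.]*", "", basename(entry))

# Decide destinations for one artifact. Single *file* count governs the flat
# branch (a lone file nested in a subdirectory still counts as single and is
# flattened); visualizations always take the directory branch.
extraction_plan <- function(artifact, outdir) {
  base <- artifact_base(artifact$source_path)
  entries <- artifact$data_entries
  if (artifact$kind != "visualization" && length(entries) == 1L) {
    data.frame(entry = entries,
               dest = file.path(outdir, paste0(base, payload_ext(entries))),
               top = file.path(outdir, paste0(base, payload_ext(entries))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(entry = entries, dest = file.path(outdir, base, entries),
               top = file.path(outdir, base), stringsAsFactors = FALSE)
  }
}

#' Extract data payloads from artifacts
#'
#' Copies every data payload out of one or more artifacts using the
#' filename-inheriting convention described above. Content is written
#' byte-for-byte and, when the archive carries a checksum manifest, verified
#' against the recorded md5 after writing. Basename collisions between input
#' artifacts are detected before anything is written.
#'
#' @param paths Character vector of artifact paths.
#' @param outdir Output directory (created if missing).
#' @param force Overwrite existing destinations instead of erroring.
#' @return Character vector of all written file paths (invisibly visible:
#'   returned normally).
#' @examples
#' \dontrun{qz_extract(c("rep-seqs.qza", "taxonomy.qza"), outdir = "out")}
#' @export
qz_extract <- function(paths, outdir = ".", force = FALSE) {
  arts <- lapply(paths, qz_load_artifact)
  bases <- vapply(paths, artifact_base, "")
  if (anyDuplicated(bases)) {
    dup <- unique(bases[duplicated(bases)])
    qz_error("qz_collision_error",
             sprintf("input artifacts share the basename '%s'; nothing extracted",
                     dup[1L]),
             basename = dup)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  plans <- lapply(arts, extraction_plan, outdir = outdir)
  for (pl in plans) {
    top <- unique(pl$top)
    if (file.exists(top) && !force) {
      qz_error("qz_exists_error",
               sprintf("destination '%s' already exists (use force = TRUE to overwrite)",
                       top),
               dest = top)
    }
  }
  written <- character()
  for (i in seq_along(arts)) {
    art <- arts[[i]]
    pl <- plans[[i]]
    root <- art$metadata$uuid
    for (j in seq_len(nrow(pl))) {
      bytes <- zq_read_raw(art$source_path,
                           paste0(root, "/data/", pl$entry[j]))
      dir.create(dirname(pl$dest[j]), recursive = TRUE, showWarnings = FALSE)
      writeBin(bytes, pl$dest[j])
      man <- art$checksum_manifest
      key <- paste0("data/", pl$entry[j])
      if (!is.null(man) && key %in% names(man) &&
          !identical(md5_file(pl$dest[j]), unname(man[[key]]))) {
        qz_error("qz_integrity_error",
                 sprintf("extracted '%s' does not match manifest md5 for %s",
                         pl$dest[j], key),
                 dest = pl$dest[j], member = key)
      }
      written <- c(written, pl$dest[j])
    }
  }
  written
}

#' Stream a text payload from an artifact
#'
#' Streams one data member to a connection. When `member` is omitted and the
#' artifact holds exactly one data file, that file streams; with several
#' files the entry list is returned with status 3 instead so callers can
#' prompt. Gzip-compressed members (`.gz`) are transparently decompressed and
#' payloads that look binary (a NUL byte within the first 4096 bytes) are
#' refused — unless `raw = TRUE`, which streams the stored bytes verbatim
#' with no decompression and no sniffing.
#'
#' @param path Artifact path.
#' @param member Data-relative payload path, or `NULL` for the single entry.
#' @param raw Stream stored bytes verbatim (no gunzip, no binary check).
#' @param con Connection or filename to stream to; `NULL` suppresses output.
#' @return (Invisibly) a list with `status` (0 streamed, 3 entry list
#'   printed), `member`, `bytes` (raw vector actually streamed), `entries`.
#' @export
qz_view <- function(path, member = NULL, raw = FALSE, con = stdout()) {
  art <- qz_load_artifact(path)
  if (is.null(member)) {
    if (length(art$data_entries) == 1L) {
      member <- art$data_entries
    } else {
      if (!is.null(con)) cat(art$data_entries, sep = "\n", file = con)
      return(invisible(list(status = 3L, member = NULL, bytes = NULL,
                            entries = art$data_entries)))
    }
  }
  if (!(member %in% art$data_entries)) {
    qz_error("qz_member_error",
             sprintf("no data member '%s' in %s; available: %s", member,
                     basename(path), paste(art$data_entries, collapse = ", ")),
             member = member, available = art$data_entries)
  }
  bytes <- zq_read_raw(art$source_path,
                       paste0(art$metadata$uuid, "/data/", member))
  if (!raw) {
    if (grepl("\\.gz$", member)) bytes <- memDecompress(bytes, type = "gzip")
    head <- bytes[seq_len(min(4096L, length(bytes)))]
    if (any(head == as.raw(0L))) {
      qz_error("qz_binary_error",
               sprintf("'%s' appears to be binary; use raw = TRUE to stream anyway",
                       member),
               member = member)
    }
  }
  if (!is.null(con)) {
    if (any(bytes == as.raw(0L))) {
      if (is.character(con)) {
        writeBin(bytes, con)
      } else {
        warning("binary content not streamed to a text connection; bytes returned invisibly",
                call. = FALSE)
      }
    } else {
      cat(rawToChar(bytes), file = con, sep = "")
    }
  }
  invisible(list(status = 0L, member = member, bytes = bytes,
                 entries = art$data_entries))
}
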