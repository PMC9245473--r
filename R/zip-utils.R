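# Internal ZIP plumbing shared by every module. Member paths inside artifact
# archives always use "/" (ZIP standard), regardless of platform.

# C-locale lexicographic sort: all deterministic ordering in the package goes
# through this so output does not depend on the session locale.
lex_sort <- function(x) sort(x, method = "radix")

md5_file <- function(path) digest::digest(file = path, algo = "md5")
md5_raw <- function(bytes) digest::digest(bytes, algo = "md5", serialize = FALSE)

# List member names, raising qz_format_error if `path` is not a readable ZIP.
zq_members <- function(path) {
  if (!file.exists(path) || dir.exists(path)) {
    qz_error("qz_format_error",
             sprintf("'%s' does not exist or is not a file", path), path = path)
  }
  lst <- tryCatch(
    zip::zip_list(path),
    error = function(e) {
      qz_error("qz_format_error",
               sprintf("'%s' is not a ZIP archive (%s)", path,
                       conditionMessage(e)),
               path = path)
    }
  )
  lst$filename
}

zq_has_member <- function(members, member) member %in% members

# Read one member fully into a raw vector. Extraction goes through a private
# temp directory; junkpaths = TRUE because we read one member at a time.
zq_read_raw <- function(path, member) {
  ex <- tempfile("qz-member-")
  dir.create(ex)
  on.exit(unlink(ex, recursive = TRUE), add = TRUE)
  got <- suppressWarnings(
    utils::unzip(path, files = member, exdir = ex, junkpaths = TRUE)
  )
  if (length(got) != 1L || !file.exists(got[[1L]])) {
    qz_error("qz_member_error",
             sprintf("member not found in archive: %s", member),
             member = member, path = path)
  }
  readBin(got[[1L]], what = "raw", n = file.size(got[[1L]]))
}

zq_read_text <- function(path, member) {
  txt <- rawToChar(zq_read_raw(path, member))
  Encoding(txt) <- "UTF-8"
  txt
}

# Zip a staged tree rooted at `stage` (containing the UUID-named root dir)
# into `out_path` atomically: write to a temp file in the destination
# directory, then rename. Member order is lexicographic for determinism.
zq_write_archive <- function(stage, out_path, fixed_mtime = NULL) {
  files <- lex_sort(list.files(stage, recursive = TRUE, all.files = TRUE,
                               no.. = TRUE))
  if (!is.null(fixed_mtime)) {
    for (f in c(files, list.dirs(stage, full.names = FALSE, recursive = TRUE))) {
      if (nzchar(f)) Sys.setFileTime(file.path(stage, f), fixed_mtime)
    }
    Sys.setFileTime(stage, fixed_mtime)
  }
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("qz-archive-", tmpdir = dirname(out_path), fileext = ".zip")
  on.exit(unlink(tmp), add = TRUE)
  old <- setwd(stage)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  zip::zip(tmp, files = files, recurse = FALSE, include_directories = FALSE,
           mode = "mirror")
  setwd(old)
  if (!file.rename(tmp, out_path)) {
    # cross-device fallback
    file.copy(tmp, out_path, overwrite = TRUE)
  }
  invisible(out_path)
}
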