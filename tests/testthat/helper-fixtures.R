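# Shared fixture suite, generated once per test run and reused everywhere.
qz_test_suite <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), paste0("qzkit-suite-", Sys.getpid()))
      cache <<- qz_standard_suite(dir, seed = 42L)
    }
    cache
  }
})

GOOD_FIXTURES <- c("import_only", "single_file", "multi_file", "chain",
                   "diamond", "visualization")

read_file_raw <- function(path) readBin(path, "raw", file.size(path))

# Independent digest oracle (tools::md5sum, not the digest package the
# implementation uses) applied to a member extracted with utils::unzip.
oracle_member_md5 <- function(archive, member) {
  ex <- withr::local_tempdir()
  utils::unzip(archive, files = member, exdir = ex)
  unname(tools::md5sum(file.path(ex, member)))
}

# Run the CLI in-process, capturing the two streams and the exit status.
run_cli <- function(args) {
  outf <- tempfile()
  errf <- tempfile()
  outc <- file(outf, "w")
  errc <- file(errf, "w")
  sink(outc)
  sink(errc, type = "message")
  status <- tryCatch(
    qz_cli(args),
    finally = {
      sink(type = "message")
      sink()
      close(outc)
      close(errc)
    })
  list(status = status, out = readLines(outf), err = readLines(errf))
}

# Write a hand-rolled (non-generator) artifact from a named list of member
# texts, for malformed/edge-case inputs the generator refuses to produce.
raw_artifact <- function(members, out_path) {
  stage <- tempfile("raw-art-")
  for (m in names(members)) {
    f <- file.path(stage, m)
    dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
    writeBin(charToRaw(members[[m]]), f)
  }
  old <- setwd(stage)
  on.exit(setwd(old), add = TRUE)
  zip::zip(out_path, files = list.files(stage, recursive = TRUE),
           recurse = FALSE, include_directories = FALSE, mode = "mirror")
  setwd(old)
  unlink(stage, recursive = TRUE)
  out_path
}

simple_version_text <- function(archive = 5L) {
  sprintf("QIIME 2\narchive: %d\nframework: 2020.8.0\n", archive)
}
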