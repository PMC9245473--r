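# Structured error conditions. Every error raised by qzkit carries a specific
# class (plus "qz_error") so callers and the CLI can dispatch on failure mode:
#
#   qz_format_error       not a ZIP archive at all
#   qz_malformed_error    ZIP, but violates the artifact layout (roots, members)
#   qz_integrity_error    internally inconsistent (root/uuid mismatch, bad md5
#                         on extraction)
#   qz_version_error      unparsable or unsupported VERSION file
#   qz_metadata_error     unparsable metadata.yaml
#   qz_validation_error   syntactic validation failure (uuid pattern, cycles)
#   qz_checksum_unsupported_error  verify requested but no manifest present
#   qz_provenance_error   missing/garbled provenance tree
#   qz_bibtex_error       unbalanced braces in a citations.bib payload
#   qz_member_error       a named archive/data member does not exist
#   qz_binary_error       refusing to stream binary content without raw = TRUE
#   qz_collision_error    two inputs map to the same output destination
#   qz_exists_error       destination exists and force = FALSE
#   qz_precondition_error a stated precondition (e.g. index.html) is unmet
#   qz_fixture_error      invalid fixture specification

qz_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "qz_error")))
}

#' @export
print.qz_error <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1L], conditionMessage(x)))
  invisible(x)
}
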