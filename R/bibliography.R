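# BibTeX handling for artifact citations.
#
# Artifacts carry the bibliography of every tool in their history as
# citations.bib members (one for the focal artifact, one per ancestor).
# Qiime2 citation keys embed plugin/version strings, so the same reference
# can recur under one key across a pipeline's artifacts, or under different
# keys across plugins; deduplication therefore matches on key OR on the
# whitespace-normalized body.
#
# The parser is deliberately brace-counting and not field-aware: bytes
# between the outer braces are preserved verbatim so arbitrary BibTeX
# round-trips unchanged (no re-wrapping, no case folding).

new_citation <- function(entry_kind, citation_key, body) {
  structure(
    list(entry_kind = entry_kind, citation_key = citation_key, body = body,
         normalized_body = trimws(gsub("[ \t\r\n]+", " ", body))),
    class = "qz_citation"
  )
}

#' Construct a BibTeX citation entry
#'
#' @param entry_kind Entry kind without the `@` (e.g. `"article"`, `"misc"`).
#' @param citation_key Non-empty citation key.
#' @param body Verbatim field text following `key,` inside the outer braces.
#' @return A `qz_citation` with the derived `normalized_body` (runs of
#'   whitespace collapsed, field order preserved).
#' @export
qz_citation <- function(entry_kind, citation_key, body = "") {
  stopifnot(is.character(citation_key), length(citation_key) == 1L,
            nzchar(citation_key))
  new_citation(entry_kind, citation_key, body)
}

#' Parse a BibTeX document into citation entries
#'
#' Scans `@kind{key, ...}` records by brace counting; nested braces inside
#' field values are preserved verbatim, and any text outside records is
#' ignored. A record whose braces never balance raises a `qz_bibtex_error`
#' carrying the byte offset where the record opened.
#'
#' @param text BibTeX source text.
#' @return List of `qz_citation` entries in file order.
#' @export
qz_parse_bibtex <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  bytes <- charToRaw(text)
  n <- length(bytes)
  at <- which(bytes == charToRaw("@"))
  open_b <- charToRaw("{")
  close_b <- charToRaw("}")
  braces <- which(bytes == open_b | bytes == close_b)
  entries <- list()
  pos <- 1L
  for (a in at) {
    if (a < pos) next
    # kind must be letters immediately after '@', then optional ws, then '{'
    rest <- substr(text, a + 1L, min(n, a + 64L))
    m <- regexec("^([A-Za-z]+)[ \t\r\n]*\\{", rest)[[1L]]
    if (m[1L] == -1L) next  # stray '@' outside a record; ignore
    kind <- substr(rest, m[2L], m[2L] + attr(m, "match.length")[2L] - 1L)
    brace_at <- a + attr(m, "match.length")[1L]
    rel <- braces[braces >= brace_at]
    delta <- ifelse(bytes[rel] == open_b, 1L, -1L)
    bal <- which(cumsum(delta) == 0L)
    if (length(bal) == 0L) {
      qz_error("qz_bibtex_error",
               sprintf("unbalanced braces: record opened at byte %d never closes",
                       a),
               offset = a)
    }
    close_at <- rel[bal[1L]]
    inner <- substr(text, brace_at + 1L, close_at - 1L)
    comma <- regexpr(",", inner, fixed = TRUE)
    if (comma == -1L) {
      key <- trimws(inner)
      body <- ""
    } else {
      key <- trimws(substr(inner, 1L, comma - 1L))
      body <- substr(inner, comma + 1L, nchar(inner))
    }
    if (!nzchar(key)) next  # @string{}-like or empty record; not a citation
    entries[[length(entries) + 1L]] <- new_citation(kind, key, body)
    pos <- close_at + 1L
  }
  entries
}

#' Serialize citation entries back to BibTeX text
#'
#' The inverse of [qz_parse_bibtex()]: bodies are emitted verbatim, never
#' re-wrapped or re-indented, so `parse(serialize(x))` preserves
#' `(entry_kind, citation_key, normalized_body)` for every entry.
#'
#' @param entries List of `qz_citation`.
#' @return A single BibTeX string.
#' @export
qz_format_bibtex <- function(entries) {
  if (length(entries) == 0L) return("")
  recs <- vapply(entries, function(e) {
    paste0("@", e$entry_kind, "{", e$citation_key,
           if (nzchar(e$body)) paste0(",", e$body) else "", "}")
  }, "")
  paste0(paste(recs, collapse = "\n\n"), "\n")
}

#' Deduplicate citation entries
#'
#' Keeps the first occurrence; a later entry is a duplicate when it shares
#' the citation key OR the whitespace-normalized body with an earlier one.
#' Two entries with the same key but different bodies keep the first and emit
#' a collision warning naming both sources. Idempotent; order-preserving.
#'
#' @param entries List of `qz_citation` (optionally carrying a `source`
#'   field naming where each came from, used in collision warnings).
#' @return Deduplicated list in first-occurrence order.
#' @export
qz_dedup_citations <- function(entries) {
  kept <- list()
  seen_keys <- character()
  seen_bodies <- character()
  key_body <- character()  # key -> normalized body of the kept entry
  key_src <- character()
  for (e in entries) {
    src <- if (is.null(e$source)) "<unknown>" else e$source
    if (e$citation_key %in% seen_keys) {
      if (!identical(key_body[[e$citation_key]], e$normalized_body)) {
        warning(sprintf(
          "citation key collision for '%s': kept entry from %s, dropped differing entry from %s",
          e$citation_key, key_src[[e$citation_key]], src), call. = FALSE)
      }
      next
    }
    if (e$normalized_body %in% seen_bodies && nzchar(e$normalized_body)) next
    kept[[length(kept) + 1L]] <- e
    seen_keys <- c(seen_keys, e$citation_key)
    if (nzchar(e$normalized_body)) seen_bodies <- c(seen_bodies, e$normalized_body)
    key_body[[e$citation_key]] <- e$normalized_body
    key_src[[e$citation_key]] <- src
  }
  kept
}

citation_members <- function(members, root) {
  pat <- paste0("^", root,
                "/provenance/(citations\\.bib|artifacts/[^/]+/citations\\.bib)$")
  hits <- members[grepl(pat, members)]
  focal <- paste0(root, "/provenance/citations.bib")
  c(hits[hits == focal], lex_sort(hits[hits != focal]))
}

#' Merge the citations carried by a set of artifacts
#'
#' Gathers every `citations.bib` member (the focal artifact's and all its
#' recorded ancestors'), parses and deduplicates across all sources, and
#' returns a merged bibliography in first-occurrence order. Artifacts without
#' citations contribute nothing and produce a notice; unreadable artifacts
#' are reported and skipped while the rest are still processed.
#'
#' @param paths Character vector of artifact paths.
#' @return A `qz_bibliography`: `entries` (deduplicated `qz_citation` list),
#'   `text` (serialized BibTeX), `notices`, `errors` (empty when everything
#'   was processed).
#' @export
qz_merge_citations <- function(paths) {
  all_entries <- list()
  notices <- character()
  errors <- character()
  for (p in paths) {
    art <- tryCatch(qz_load_artifact(p), error = function(e) e)
    if (inherits(art, "error")) {
      errors <- c(errors, sprintf("%s: %s", p, conditionMessage(art)))
      next
    }
    members <- zq_members(art$source_path)
    bibs <- citation_members(members, art$metadata$uuid)
    count <- 0L
    for (b in bibs) {
      es <- qz_parse_bibtex(zq_read_text(art$source_path, b))
      es <- lapply(es, function(e) {
        e$source <- sprintf("%s:%s", basename(p), b)
        e
      })
      count <- count + length(es)
      all_entries <- c(all_entries, es)
    }
    if (count == 0L) {
      notices <- c(notices, sprintf("%s: no citations found", p))
    }
  }
  entries <- qz_dedup_citations(all_entries)
  structure(
    list(entries = entries, text = qz_format_bibtex(entries),
         notices = notices, errors = errors),
    class = "qz_bibliography"
  )
}

#' @export
print.qz_bibliography <- function(x, ...) {
  cat(sprintf("<qz_bibliography> %d unique entr%s\n", length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies"))
  for (n in x$notices) cat(sprintf("  notice: %s\n", n))
  for (e in x$errors) cat(sprintf("  error: %s\n", e))
  invisible(x)
}
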