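chain_action_yaml <- function(inputs = NULL, type = "method",
                              plugin = "dada2", action = "denoise-single") {
  paste0(
    "action:\n",
    "  type: ", type, "\n",
    if (!is.null(plugin)) paste0("  plugin: ", plugin, "\n") else "",
    "  action: ", action, "\n",
    if (!is.null(inputs)) {
      paste0("  inputs:\n",
             paste(sprintf("  - %s: %s", names(inputs), inputs),
                   collapse = "\n"), "\n")
    } else "",
    "  parameters:\n  - trunc_len: 240\n")
}

test_that("qz_parse_action parses kinds, ordered inputs, and parameters", {
  imp <- qz_parse_action("action:\n  type: import\n  format: FastqGzFormat\n")
  expect_identical(imp$action_kind, "import")
  expect_length(imp$inputs, 0L)
  expect_false(imp$kind_fallback)

  u1 <- "11111111-1111-4111-8111-111111111111"
  u2 <- "22222222-2222-4222-8222-222222222222"
  a <- qz_parse_action(chain_action_yaml(c(demultiplexed_seqs = u1)))
  expect_identical(a$inputs, c(demultiplexed_seqs = u1))
  expect_identical(a$plugin, "dada2")
  expect_identical(a$parameters, c(trunc_len = "240"))

  # file order of inputs is preserved
  two <- qz_parse_action(chain_action_yaml(c(b_second = u2, a_first = u1)))
  expect_identical(names(two$inputs), c("b_second", "a_first"))

  unk <- qz_parse_action("action:\n  type: frobnicate\n")
  expect_identical(unk$action_kind, "frobnicate")
  expect_true(unk$kind_fallback)

  expect_error(
    qz_parse_action(paste0("action:\n  type: import\n  inputs:\n  - x: ", u1,
                           "\n")),
    class = "qz_validation_error")
  expect_error(qz_parse_action("action:\n  inputs:\n  - x: not-a-uuid\n"),
               class = "qz_validation_error")
  expect_error(qz_parse_action("no action mapping: true\n"),
               class = "qz_provenance_error")
  expect_error(qz_parse_action("action: [unclosed\n"),
               class = "qz_provenance_error")
})

test_that("qz_build_graph reproduces the generator-recorded node and edge sets", {
  recs <- qz_test_suite()
  cases <- list(
    list(rec = recs$import_only, n_nodes = 1L, n_edges = 0L),
    list(rec = recs$chain, n_nodes = 3L, n_edges = 2L),
    list(rec = recs$diamond, n_nodes = 4L, n_edges = 4L))
  for (cs in cases) {
    r <- cs$rec
    g <- qz_build_graph(r$path)
    expect_setequal(names(g$nodes), r$uuids)
    expect_length(g$nodes, cs$n_nodes)
    expect_identical(nrow(g$edges), cs$n_edges)
    got <- paste(g$edges$from, g$edges$to, g$edges$label)
    want <- paste(r$adjacency$from, r$adjacency$to, r$adjacency$param)
    expect_setequal(got, want)
    expect_identical(g$focal, r$focal_uuid)
    expect_identical(sum(vapply(g$nodes, `[[`, TRUE, "is_focal")), 1L)
    # topological order is a permutation of the nodes with edges respected
    for (i in seq_len(nrow(g$edges))) {
      expect_lt(match(g$edges$from[i], g$order),
                match(g$edges$to[i], g$order))
    }
  }
})

test_that("a dangling input reference becomes a stub node with a warning", {
  ghost <- "eeeeeeee-aaaa-4aaa-8aaa-eeeeeeeeeeee"
  root <- "5e2d1c3a-0000-4000-8000-0000000000aa"
  path <- raw_artifact(
    stats::setNames(
      list(simple_version_text(4L),
           paste0("uuid: ", root, "\ntype: FeatureData[Sequence]\n",
                  "format: DNASequencesDirectoryFormat\n"),
           ">a\nACGT\n",
           paste0("uuid: ", root, "\ntype: FeatureData[Sequence]\n",
                  "format: DNASequencesDirectoryFormat\n"),
           chain_action_yaml(c(reads = ghost))),
      paste0(root, "/", c("VERSION", "metadata.yaml", "data/x.fasta",
                          "provenance/metadata.yaml",
                          "provenance/action/action.yaml"))),
    tempfile(fileext = ".qza"))
  g <- qz_build_graph(path)
  expect_setequal(names(g$nodes), c(root, ghost))
  expect_null(g$nodes[[ghost]]$metadata)
  expect_true(any(grepl("dangling", g$warnings)))
  expect_identical(nrow(g$edges), 1L)
})

test_that("artifacts without provenance raise qz_provenance_error", {
  root <- "5e2d1c3a-0000-4000-8000-0000000000bb"
  path <- raw_artifact(
    stats::setNames(
      list(simple_version_text(4L),
           paste0("uuid: ", root,
                  "\ntype: FeatureData[Sequence]\nformat: Fmt\n"),
           ">a\nACGT\n"),
      paste0(root, "/", c("VERSION", "metadata.yaml", "data/x.fasta"))),
    tempfile(fileext = ".qza"))
  expect_error(qz_build_graph(path), class = "qz_provenance_error")
})

test_that("qz_render_listing orders topologically with uuid tie-break", {
  recs <- qz_test_suite()

  chain <- qz_build_graph(recs$chain$path)
  lines <- qz_render_listing(chain)
  expect_length(lines, 3L)
  cols <- strsplit(lines, "\t", fixed = TRUE)
  expect_identical(cols[[1L]][1L], recs$chain$uuids[[1L]])  # import first
  expect_identical(cols[[3L]][1L], recs$chain$focal_uuid)   # focal last
  expect_identical(cols[[1L]][4L], "import")
  expect_identical(cols[[3L]][6L], "*")
  expect_false(any(grepl("\\*$", lines[1:2])))

  single <- qz_build_graph(recs$import_only$path)
  sl <- qz_render_listing(single)
  expect_length(sl, 1L)
  expect_identical(strsplit(sl, "\t")[[1L]][6L], "*")

  dia <- qz_build_graph(recs$diamond$path)
  dl <- strsplit(qz_render_listing(dia), "\t")
  ids <- vapply(dl, `[[`, "", 1L)
  expect_identical(ids[1L], recs$diamond$uuids[[1L]])
  expect_identical(ids[4L], recs$diamond$focal_uuid)
  middle <- sort(recs$diamond$uuids[2:3], method = "radix")
  expect_identical(ids[2:3], middle)

  # verbose mode appends parameter lines
  expect_gt(length(qz_render_listing(chain, verbose = TRUE)), length(lines))
})

test_that("qz_to_dot emits deterministic, brace-balanced DOT", {
  recs <- qz_test_suite()
  for (nm in c("import_only", "chain", "diamond")) {
    g <- qz_build_graph(recs[[nm]]$path)
    dot <- qz_to_dot(g)
    expect_identical(dot, qz_to_dot(g), info = nm)  # byte-deterministic
    expect_match(dot, "^digraph")
    n_open <- lengths(regmatches(dot, gregexpr("{", dot, fixed = TRUE)))
    n_close <- lengths(regmatches(dot, gregexpr("}", dot, fixed = TRUE)))
    expect_identical(n_open, n_close, info = nm)

    lines <- strsplit(dot, "\n")[[1L]]
    node_stmts <- grep('^  "[0-9a-f-]{36}" \\[', lines)
    edge_stmts <- grep(" -> ", lines, fixed = TRUE)
    expect_length(node_stmts, length(recs[[nm]]$uuids))
    expect_length(edge_stmts, nrow(recs[[nm]]$adjacency))
    # focal node visually distinguished
    expect_identical(sum(grepl("fillcolor", lines)), 1L)
  }
})
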