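test_that("the bipartite graph carries one canonical link and per-synonym links", {
  df <- data.frame(locus_tag = "BSU33690", canonical = "opuCB",
                   stringsAsFactors = FALSE)
  df$synonyms <- list("yvbD")
  dict <- identity_dictionary(df)
  g <- build_bipartite(dict)
  expect_equal(nrow(g$links), 2L)
  expect_true(any(g$links$name == "opuCB" & g$links$locus_tag == "BSU33690" &
                    g$links$kind == "canonical"))
  expect_true(any(g$links$name == "yvbD" & g$links$locus_tag == "BSU33690" &
                    g$links$kind == "synonym"))
})

test_that("an empty dictionary yields an empty graph", {
  g <- build_bipartite(identity_dictionary(
    data.frame(locus_tag = character(0), canonical = character(0))))
  expect_equal(nrow(g$links), 0L)
  expect_length(g$name_nodes, 0)
})

test_that("a synonym shared by two locus tags has bipartite degree two", {
  df <- data.frame(locus_tag = c("L1", "L2"), canonical = c("geneA", "geneB"),
                   stringsAsFactors = FALSE)
  df$synonyms <- list("shared", "shared")
  g <- build_bipartite(identity_dictionary(df))
  expect_equal(sum(g$links$name == "shared"), 2L)
})

test_that("duplicate locus tags are rejected with their names", {
  df <- data.frame(locus_tag = c("L1", "L1"), canonical = c("a", "b"),
                   stringsAsFactors = FALSE)
  expect_error(identity_dictionary(df), "L1")
})

test_that("canonical names fall back to the locus tag", {
  dict <- identity_dictionary(data.frame(
    locus_tag = c("L1", "L2"), canonical = c("geneA", NA),
    stringsAsFactors = FALSE))
  expect_equal(dict$entries$canonical, c("geneA", "L2"))
})

test_that("the published disambiguation outcomes are reproduced", {
  g <- build_bipartite(fig3_dictionary())
  res <- resolve_symbols(
    c("opuCB", "dnaE", "dnaG", "dnaN", "dnaA", "dnaX", "yvbD", "dnaH"), g)
  # the six canonical names resolve directly
  expect_equal(unname(res$mapping[c("opuCB", "dnaE", "dnaG", "dnaN", "dnaA", "dnaX")]),
               c("BSU33690", "BSU16170", "BSU25490", "BSU00020", "BSU00010", "BSU00030"))
  # yvbD has degree one, so it merges into opuCB's locus tag
  expect_equal(unname(res$mapping[["yvbD"]]), "BSU33690")
  # dnaH is degenerate (two locus tags, no canonical link) -> taboo
  expect_equal(res$taboo, "dnaH")
  expect_equal(unname(res$canonical_of[["BSU33690"]]), "opuCB")
})

test_that("locus tags win over names, and case fallback is a last resort", {
  df <- data.frame(locus_tag = c("abcX", "L2"), canonical = c("gene1", "gene2"),
                   stringsAsFactors = FALSE)
  df$synonyms <- list(character(0), "abcX")  # a synonym spelled like a locus tag
  g <- build_bipartite(identity_dictionary(df))
  res <- resolve_symbols(c("abcX", "GENE2", "nothere"), g)
  expect_equal(unname(res$mapping[["abcX"]]), "abcX")   # locus tag wins
  expect_equal(unname(res$mapping[["GENE2"]]), "L2")    # case-insensitive retry
  expect_true("nothere" %in% res$taboo)                  # absent symbols reported
  st <- res$detail$status[res$detail$symbol == "nothere"]
  expect_equal(st, "taboo_unknown")
})

test_that("resolution is single-valued on generated dictionaries", {
  for (seed in 1:5) {
    gen <- generate_identity_dictionary(30, 12, 4, seed = seed)
    g <- build_bipartite(gen$dictionary)
    syms <- c(g$locus_nodes, g$name_nodes)
    res <- resolve_symbols(syms, g)
    expect_length(intersect(names(res$mapping), res$taboo), 0)
    expect_false(anyDuplicated(names(res$mapping)) > 0)
    expect_setequal(res$taboo, gen$taboo)
  }
})

test_that("synonym nodes collapse into a single locus-tag node", {
  g <- build_bipartite(fig3_dictionary())
  net <- make_net(list("r", "yvbD", "activation", "weak"),
                  list("r", "opuCB", "activation", "strong"))
  res <- resolve_symbols(net$nodes$id, g)
  out <- collapse_synonym_nodes(net, res)
  expect_setequal(out$nodes$id, c("BSU33690", "r"))
  expect_equal(nrow(out$edges), 1L)
  # the merged duplicate edge keeps the stronger evidence
  expect_equal(out$edges$evidence, "strong")
  node <- out$nodes[out$nodes$id == "BSU33690", ]
  expect_equal(node$canonical, "opuCB")
  expect_true("yvbD" %in% node$synonyms[[1]])
  # node count law: distinct resolved locus tags + taboo symbols
  resolved_loci <- unique(stats::na.omit(unname(res$mapping[net$nodes$id])))
  expect_equal(nrow(out$nodes),
               length(resolved_loci) + sum(net$nodes$id %in% res$taboo))
})

test_that("collapsing a synonym-free network changes nothing", {
  df <- data.frame(locus_tag = c("A", "B"), canonical = c("A", "B"),
                   stringsAsFactors = FALSE)
  g <- build_bipartite(identity_dictionary(df))
  net <- make_net(list("A", "B", "activation", "weak"))
  res <- resolve_symbols(net$nodes$id, g)
  out <- collapse_synonym_nodes(net, res)
  out$metadata$resolved <- NULL
  expected <- net
  expected$nodes$locus_tag <- expected$nodes$id  # ids recognised as locus tags
  expect_same_network(out, expected)
})

test_that("collapsing is independent of input order", {
  g <- build_bipartite(fig3_dictionary())
  rows <- edges_df(list("r", "yvbD", "activation", "weak"),
                   list("r", "opuCB", "activation", "strong"),
                   list("dnaA", "dnaN", "repression", "weak"))
  n1 <- add_interactions(regnet(), rows)
  n2 <- add_interactions(regnet(), rows[c(3, 1, 2), ])
  r1 <- resolve_symbols(n1$nodes$id, g)
  r2 <- resolve_symbols(rev(n2$nodes$id), g)
  expect_same_network(collapse_synonym_nodes(n1, r1),
                      collapse_synonym_nodes(n2, r2))
})
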