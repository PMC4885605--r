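test_that("adding interactions deduplicates and is idempotent", {
  rows <- edges_df(list("A", "B", "activation", "weak"),
                   list("A", "B", "activation", "weak"))
  net <- add_interactions(regnet(), rows)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$effect, "activation")
  # applying the same rows twice equals applying them once
  expect_same_network(add_interactions(net, rows), net)
})

test_that("conflicting effects merge to dual and evidence never downgrades", {
  net <- make_net(list("A", "B", "activation", "weak"),
                  list("A", "B", "repression", "strong"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$effect, "dual")
  expect_equal(net$edges$evidence, "strong")
  # unknown is the bottom of both lattices
  net2 <- make_net(list("A", "B", "unknown", "unknown"),
                   list("A", "B", "repression", "weak"))
  expect_equal(net2$edges$effect, "repression")
  expect_equal(net2$edges$evidence, "weak")
})

test_that("sigma-factor regulators always activate", {
  net <- make_net(list("sigA", "B", "repression", "strong"))
  net <- set_sigma_factors(net, "sigA")
  expect_equal(net$edges$effect, "activation")
  # rule also applies to edges added after flagging
  net <- add_interactions(net, edges_df(list("sigA", "C", "repression", "weak")))
  expect_true(all(net$edges$effect == "activation"))
})

test_that("malformed interaction rows are reported with their row index", {
  rows <- data.frame(regulator = c("A", NA), target = c("B", "C"),
                     stringsAsFactors = FALSE)
  expect_error(add_interactions(regnet(), rows), "row 2")
  rows2 <- data.frame(regulator = c("A", "B"), target = c("B", ""),
                      stringsAsFactors = FALSE)
  expect_error(add_interactions(regnet(), rows2), "row 2")
})

test_that("dependent complexes fully replace their subunit genes", {
  net <- make_net(list("r", "s1", "activation", "strong"),
                  list("r", "s2", "activation", "strong"),
                  list("s1", "t", "activation", "weak"),
                  list("s2", "t", "activation", "weak"))
  defs <- data.frame(complex_id = "C", subunits = "s1|s2", targets = "t",
                     stringsAsFactors = FALSE)
  out <- collapse_complexes(net, defs)
  expect_setequal(out$nodes$id, c("r", "C", "t"))
  expect_equal(nrow(out$edges), 2L)
  expect_true(any(out$edges$source == "r" & out$edges$target == "C"))
  expect_true(any(out$edges$source == "C" & out$edges$target == "t"))
  expect_equal(out$nodes$kind[out$nodes$id == "C"], "complex")
})

test_that("independently acting subunits keep their own regulation", {
  net <- make_net(list("r", "s1", "activation", "strong"),
                  list("r", "s2", "activation", "strong"),
                  list("s1", "t", "activation", "weak"),
                  list("s2", "t", "activation", "weak"),
                  list("s1", "u", "repression", "strong"))
  defs <- data.frame(complex_id = "C", subunits = "s1|s2", targets = "t",
                     stringsAsFactors = FALSE)
  out <- collapse_complexes(net, defs)
  expect_setequal(out$nodes$id, c("r", "s1", "s2", "C", "t", "u"))
  has_edge <- function(s, t) any(out$edges$source == s & out$edges$target == t)
  expect_true(has_edge("s1", "C") && has_edge("s2", "C"))
  expect_equal(out$edges$effect[out$edges$source == "s1" & out$edges$target == "C"],
               "activation")
  expect_true(has_edge("s1", "u"))
  expect_true(has_edge("C", "t"))
  expect_false(has_edge("s1", "t"))
  expect_true(has_edge("r", "s1") && has_edge("r", "s2"))
})

test_that("collapsing with no definitions is the identity", {
  net <- make_net(list("A", "B"))
  expect_same_network(collapse_complexes(net, NULL), net)
  expect_same_network(collapse_complexes(net, data.frame()), net)
})

test_that("complex definitions are validated", {
  net <- make_net(list("r", "s1"))
  expect_error(collapse_complexes(net, data.frame(
    complex_id = "C", subunits = "s1", targets = "", stringsAsFactors = FALSE)),
    "at least 2 subunits")
  expect_error(collapse_complexes(net, data.frame(
    complex_id = "C", subunits = "s1|ghost", targets = "", stringsAsFactors = FALSE)),
    "ghost")
})

test_that("collapsing complexes preserves regulated targets reachable from outside", {
  net <- make_net(list("r", "s1", "activation", "strong"),
                  list("r", "s2", "activation", "strong"),
                  list("s1", "t", "activation", "weak"),
                  list("s2", "t", "activation", "weak"),
                  list("r", "x", "activation", "weak"))
  defs <- data.frame(complex_id = "C", subunits = "s1|s2", targets = "t",
                     stringsAsFactors = FALSE)
  out <- collapse_complexes(net, defs)
  reach <- function(n, from) {
    g <- as_igraph(n)
    names(igraph::subcomponent(g, from, mode = "out"))
  }
  # every non-subunit gene reachable from r before is still reachable
  before <- setdiff(reach(net, "r"), c("s1", "s2", "r"))
  after <- setdiff(reach(out, "r"), c("C", "r"))
  expect_setequal(after, before)
})

test_that("genomic coverage counts gene nodes only", {
  rows <- data.frame(regulator = "g1", target = paste0("g", 2:100),
                     stringsAsFactors = FALSE)
  net <- add_interactions(regnet(genome_gene_count = 500), rows)
  # independent subunit activity keeps the genes when complexes are added
  net <- add_interactions(net, edges_df(
    list("g2", "g8"), list("g4", "g9"), list("g6", "g10")))
  expect_equal(genomic_coverage(net), 20)
  # complexes are composites of already-counted genes
  defs <- data.frame(complex_id = paste0("C", 1:3),
                     subunits = c("g2|g3", "g4|g5", "g6|g7"),
                     targets = "", stringsAsFactors = FALSE)
  net2 <- collapse_complexes(net, defs)
  expect_equal(sum(net2$nodes$kind == "complex"), 3L)
  expect_equal(sum(net2$nodes$kind == "gene"), 100L)
  expect_equal(genomic_coverage(net2), 20)
  expect_error(genomic_coverage(make_net(list("A", "B"))), "genome_gene_count")
})

test_that("evidence projection keeps strong edges and drops isolated nodes", {
  net <- make_net(list("A", "B", "activation", "strong"),
                  list("A", "C", "activation", "strong"),
                  list("C", "D", "repression", "weak"),
                  list("D", "E", "repression", "weak"),
                  list("E", "F", "repression", "unknown"))
  strong <- project_subnetwork(net, evidence = "strong")
  expect_equal(nrow(strong$edges), 2L)
  expect_setequal(strong$nodes$id, c("A", "B", "C"))
  # monotone: projected edges are a subset of the full edge set
  expect_true(all(paste(strong$edges$source, strong$edges$target) %in%
                    paste(net$edges$source, net$edges$target)))
  # all-weak network projects to the empty network
  weak <- make_net(list("A", "B", "activation", "weak"))
  empty <- project_subnetwork(weak, evidence = "strong")
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("module projection recovers exactly the planted module", {
  p <- generate_planted_network(planted_network_spec(seed = 3))
  d <- nda_decompose(p$network)
  net <- apply_decomposition(p$network, d)
  mod <- names(p$partition)[1]
  sub <- project_subnetwork(net, module = mod)
  expect_setequal(sub$nodes$id, p$partition[[mod]])
  expect_true(all(sub$edges$source %in% p$partition[[mod]] &
                    sub$edges$target %in% p$partition[[mod]]))
  expect_error(project_subnetwork(net, module = "no-such-module"), "unknown module")
})

test_that("JSON serialization round-trips networks field-for-field", {
  empty <- regnet("nobody", metadata = list(sources = character(0)))
  doc <- jsonlite::fromJSON(write_regnet_json(empty), simplifyVector = FALSE)
  expect_length(doc$nodes, 0)
  expect_length(doc$edges, 0)

  net <- make_net(list("A", "B", "activation", "strong"),
                  organism = "toy", genome = 10L)
  expect_same_network(read_regnet_json(write_regnet_json(net)), net)

  # a richer model: synonyms, sigma flags, class annotations
  p <- generate_planted_network(planted_network_spec(seed = 5))
  net2 <- apply_decomposition(p$network, nda_decompose(p$network))
  net2$nodes$synonyms[[1]] <- c("alias1", "alias2")
  net2$metadata$sources <- c("setA", "setB")
  expect_same_network(read_regnet_json(write_regnet_json(net2)), net2)
})

test_that("JSON schema violations are reported with their path", {
  bad <- '{"metadata":{"organism":"x"},
           "nodes":[{"id":"A"}],
           "edges":[{"source":"A","target":"B"}]}'
  expect_error(read_regnet_json(bad), "\\$\\.edges\\[1\\]\\.target")
  dup <- '{"metadata":{"organism":"x"},
           "nodes":[{"id":"A"},{"id":"A"}],
           "edges":[]}'
  expect_error(read_regnet_json(dup), "\\$\\.nodes\\[2\\]\\.id")
  expect_error(read_regnet_json('{"nodes":[],"edges":[]}'), "\\$\\.metadata")
})
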