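test_that("one strong evidence code makes an interaction strong", {
  scheme <- evidence_scheme(
    strong_codes = c("footprinting with purified protein", "site mutation"),
    weak_codes = c("gel shift with extracts", "expression analysis"))
  expect_equal(classify_evidence("footprinting with purified protein", scheme), "strong")
  expect_equal(classify_evidence(
    c("gel shift with extracts", "expression analysis"), scheme), "weak")
  expect_equal(classify_evidence(character(0), scheme), "weak")
  # codes absent from the scheme are not strong
  expect_equal(classify_evidence("mystery assay", scheme), "weak")
  expect_error(evidence_scheme("a", c("a", "b")), "both strong and weak")
})

test_that("merging a model with itself is the identity", {
  tri <- fixture_triple()
  expect_same_network(merge_networks(list(tri$m1, tri$m1)), tri$m1)
})

test_that("merging reconciles effects and evidences through the lattices", {
  m1 <- make_net(list("A", "B", "activation", "weak"))
  m2 <- make_net(list("A", "B", "repression", "strong"))
  out <- merge_networks(list(m1, m2))
  expect_equal(nrow(out$edges), 1L)
  expect_equal(out$edges$effect, "dual")
  expect_equal(out$edges$evidence, "strong")
})

test_that("disjoint models merge to the union of their edges", {
  m1 <- add_interactions(regnet(), data.frame(
    regulator = paste0("a", 1:5), target = paste0("b", 1:5)))
  m2 <- add_interactions(regnet(), data.frame(
    regulator = paste0("c", 1:7), target = paste0("d", 1:7)))
  out <- merge_networks(list(m1, m2))
  expect_equal(nrow(out$edges), 12L)
})

test_that("merging is commutative and associative up to field equality", {
  tri <- fixture_triple()
  ms <- list(tri$m1, tri$m2, tri$m3)
  expect_same_network(merge_networks(ms),
                      merge_networks(rev(ms)))
  left <- merge_networks(list(merge_networks(list(tri$m1, tri$m2)), tri$m3))
  right <- merge_networks(list(tri$m1, merge_networks(list(tri$m2, tri$m3))))
  expect_same_network(left, right)
  expect_same_network(left, merge_networks(ms))
})

test_that("merged edge counts are bounded and evidence is monotone", {
  tri <- fixture_triple()
  ms <- list(tri$m1, tri$m2, tri$m3)
  out <- merge_networks(ms)
  expect_lte(nrow(out$edges), sum(vapply(ms, function(m) nrow(m$edges), 0L)))
  rank <- function(e) match(e, c("unknown", "weak", "strong"))
  for (m in ms) {
    for (i in seq_len(nrow(m$edges))) {
      j <- which(out$edges$source == m$edges$source[i] &
                   out$edges$target == m$edges$target[i])
      expect_gte(rank(out$edges$evidence[j]), rank(m$edges$evidence[i]))
    }
  }
  # equality holds exactly for pairwise edge-disjoint models
  d1 <- make_net(list("p", "q")); d2 <- make_net(list("r", "s"))
  expect_equal(nrow(merge_networks(list(d1, d2))$edges), 2L)
})

test_that("unresolved models can be refused", {
  tri <- fixture_triple()
  expect_error(merge_networks(list(tri$m1, tri$m2), require_resolved = TRUE),
               "resolve")
})

test_that("overlap statistics count shared and exclusive elements exactly", {
  tri <- fixture_triple()
  ov <- overlap_stats(list(one = tri$m1, two = tri$m1))
  expect_equal(ov$pairwise$shared_nodes, nrow(tri$m1$nodes))
  expect_equal(ov$pairwise$shared_edges, nrow(tri$m1$edges))

  d1 <- make_net(list("p", "q")); d2 <- make_net(list("r", "s"))
  ov2 <- overlap_stats(list(d1, d2))
  expect_equal(ov2$pairwise$shared_nodes, 0L)
  expect_equal(ov2$pairwise$shared_edges, 0L)

  # a triple with a planted 10-edge pairwise overlap
  shared <- data.frame(regulator = "hub", target = paste0("t", 1:10))
  own <- function(tag) data.frame(regulator = tag, target = paste0(tag, 1:3))
  mA <- add_interactions(regnet(), rbind(shared, own("A")))
  mB <- add_interactions(regnet(), rbind(shared, own("B")))
  mC <- add_interactions(regnet(), rbind(shared, own("C")))
  ov3 <- overlap_stats(list(A = mA, B = mB, C = mC))
  expect_true(all(ov3$pairwise$shared_edges == 10L))
  reg <- ov3$edge_regions
  expect_equal(reg$count[reg$subset == "A&B&C"], 10L)
  expect_equal(reg$count[reg$subset == "A"], 3L)
  # shared counts never exceed the smaller model
  expect_true(all(ov3$pairwise$shared_edges <=
                    pmin(nrow(mA$edges), nrow(mB$edges))))
})

test_that("containment detects fully included datasets", {
  tri <- fixture_triple()
  sub <- tri$m1
  sub$edges <- sub$edges[1, , drop = FALSE]
  sub$nodes <- sub$nodes[sub$nodes$id %in% c(sub$edges$source, sub$edges$target), ]
  expect_true(containment_check(sub, tri$m1))
  extra <- add_interactions(sub, edges_df(list("Z", "W")))
  expect_false(containment_check(extra, tri$m1))
  expect_true(containment_check(regnet(), tri$m1))
})

test_that("small networks are filtered by gene count", {
  mk <- function(n) add_interactions(regnet(), data.frame(
    regulator = "r", target = paste0("g", seq_len(n - 1L))))
  models <- list(small = mk(50), edge = mk(110), big = mk(200))
  out <- filter_small_networks(models, min_genes = 110)
  expect_setequal(names(out$kept), c("edge", "big"))
  expect_equal(out$report$kept, c(FALSE, TRUE, TRUE))
  expect_length(filter_small_networks(list())$kept, 0)
  all_kept <- filter_small_networks(models, min_genes = 1)
  expect_length(all_kept$kept, 3)
})
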