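test_that("the kappa closed form matches hand values and the root oracle", {
  expect_equal(kappa_threshold(1, 1), 1)
  expect_equal(kappa_threshold(4, 1), 2)
  # bisection oracle on the derivative of the fitted curve
  deriv_root <- function(a, b) {
    uniroot(function(k) a * b * k^(-b - 1) - 1,
            interval = c(1e-9, 1e6), tol = 1e-12)$root
  }
  expect_equal(kappa_threshold(8, 2), 16^(1 / 3), tolerance = 1e-12)
  expect_equal(kappa_threshold(8, 2), deriv_root(8, 2), tolerance = 1e-9)
  set.seed(3)
  for (i in 1:25) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(kappa_threshold(a, b), deriv_root(a, b), tolerance = 1e-9)
  }
})

test_that("kappa computed from a planted network separates hubs from module TFs", {
  p <- generate_planted_network(planted_network_spec(seed = 4))
  kr <- compute_kappa(p$network)
  k <- regnda:::out_degrees(p$network)
  grs <- names(p$classification)[p$classification == "global_regulator"]
  expect_lt(max(k[setdiff(names(k), grs)]), kr$kappa)
  expect_gt(min(k[grs]), kr$kappa)
  expect_setequal(identify_global_regulators(p$network, kr), grs)
  # kappa is reproduced by its own fit's closed form
  expect_equal(kr$kappa, kappa_threshold(kr$a, kr$b))
})

test_that("kappa fails informatively when degree diversity is insufficient", {
  chain <- make_net(list("A", "B"), list("B", "C"))
  expect_error(compute_kappa(chain), "degree diversity")
})

test_that("no node exceeds kappa in a hub-free network", {
  net <- make_net(list("A", "B"), list("B", "C"), list("C", "A"))
  expect_length(identify_global_regulators(net, 5), 0)
})

test_that("the decomposition classifies a hand-traced example correctly", {
  # GR regulates only m; two TF modules; x reads both modules
  net <- make_net(list("GR", "m"),
                  list("tf1", "a"), list("tf1", "b"),
                  list("tf2", "c"), list("tf2", "d"),
                  list("tf1", "x"), list("tf2", "x"))
  d <- nda_decompose(net, global_regulators = "GR")
  cls <- d$classification
  expect_equal(unname(cls["GR"]), "global_regulator")
  expect_equal(unname(cls["m"]), "basal_machinery")
  expect_equal(unname(cls["x"]), "intermodular")
  expect_setequal(names(cls)[cls == "modular"], c("tf1", "a", "b", "tf2", "c", "d"))
  expect_length(d$partition, 2)
  mods <- lapply(d$partition, sort)
  expect_true(any(vapply(mods, identical, logical(1), y = c("a", "b", "tf1"))))
  expect_true(any(vapply(mods, identical, logical(1), y = c("c", "d", "tf2"))))
})

test_that("a single module with no global regulator stays one module", {
  net <- make_net(list("tf1", "tf2"), list("tf1", "a"), list("tf2", "b"))
  d <- nda_decompose(net, global_regulators = character(0))
  expect_true(all(d$classification == "modular"))
  expect_length(d$partition, 1)
  expect_equal(names(d$partition), "1.1")
})

test_that("a TF regulated only by global regulators forms its own module", {
  # t has regulatory output, so it cannot be basal machinery
  net <- make_net(list("GR", "t"), list("t", "g"), list("GR", "g2"))
  d <- nda_decompose(net, global_regulators = "GR")
  expect_equal(unname(d$classification["t"]), "modular")
  expect_equal(unname(d$classification["g"]), "modular")
  expect_equal(unname(d$classification["g2"]), "basal_machinery")
  # and no basal gene ever has regulatory output
  k <- regnda:::out_degrees(net)
  basal <- names(d$classification)[d$classification == "basal_machinery"]
  expect_true(all(k[basal] == 0))
})

test_that("degenerate inputs yield empty layers, not errors", {
  net <- make_net(list("A", "B"), list("A", "C"))
  d_all <- nda_decompose(net, global_regulators = c("A", "B", "C"))
  expect_true(all(d_all$classification == "global_regulator"))
  expect_length(d_all$partition, 0)
  layers <- architecture_layers(d_all)
  expect_length(layers$processing, 0)
  expect_length(layers$integration, 0)
})

test_that("architecture layers relabel the four classes", {
  p <- generate_planted_network(planted_network_spec(seed = 6))
  d <- nda_decompose(p$network)
  layers <- architecture_layers(d)
  expect_setequal(layers$coordination, d$global_regulators)
  expect_identical(layers$processing, d$partition)
  expect_setequal(layers$integration,
                  names(d$classification)[d$classification == "intermodular"])
  expect_setequal(layers$basal_machinery,
                  names(d$classification)[d$classification == "basal_machinery"])
  # a fixture without intermodular genes has an empty integration layer
  p0 <- generate_planted_network(planted_network_spec(n_intermodular = 0, seed = 6))
  d0 <- nda_decompose(p0$network)
  expect_length(architecture_layers(d0)$integration, 0)
})

test_that("classes partition the node set and modules exclude other classes", {
  for (seed in c(1, 9)) {
    p <- generate_planted_network(planted_network_spec(
      seed = seed, edge_noise_rate = 0.05))
    d <- nda_decompose(p$network)
    cls <- d$classification
    expect_setequal(names(cls), p$network$nodes$id)
    expect_true(all(cls %in% c("global_regulator", "modular",
                               "basal_machinery", "intermodular")))
    in_modules <- unlist(d$partition)
    expect_false(anyDuplicated(in_modules) > 0)
    expect_setequal(in_modules, names(cls)[cls == "modular"])
  }
})

test_that("removing regulators and intermodular genes disconnects the modules", {
  p <- generate_planted_network(planted_network_spec(seed = 8))
  d <- nda_decompose(p$network)
  drop <- c(d$global_regulators,
            names(d$classification)[d$classification == "intermodular"])
  g <- as_igraph(p$network)
  g <- igraph::delete_vertices(g, drop)
  comp <- igraph::components(g, mode = "weak")$membership
  for (i in seq_along(d$partition)) {
    for (j in seq_len(i - 1L)) {
      ci <- unique(comp[d$partition[[i]]])
      cj <- unique(comp[d$partition[[j]]])
      expect_length(intersect(ci, cj), 0)
    }
  }
})

test_that("planted ground truth is recovered across seeds", {
  for (seed in c(2, 5, 12)) {
    p <- generate_planted_network(planted_network_spec(seed = seed))
    d <- nda_decompose(p$network)
    expect_equal(mean(d$classification[names(p$classification)] ==
                        p$classification), 1)
    expect_equal(lapply(d$partition, sort), lapply(p$partition, sort))
  }
})
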