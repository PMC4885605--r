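# shared fixtures, all built in code

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# quick edge-list constructor
edges_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(regulator = r[[1]], target = r[[2]],
               effect = if (length(r) > 2) r[[3]] else "unknown",
               evidence = if (length(r) > 3) r[[4]] else "unknown",
               stringsAsFactors = FALSE)
  }))
}

make_net <- function(..., organism = "", genome = NA_integer_) {
  add_interactions(regnet(organism, genome), edges_df(...))
}

# dictionary mirroring the published disambiguation example: six genes
# resolvable via canonical names, yvbD a unique synonym of opuCB, and
# dnaH a degenerate synonym shared by two locus tags
fig3_dictionary <- function() {
  df <- data.frame(
    locus_tag = c("BSU33690", "BSU16170", "BSU25490", "BSU00020",
                  "BSU00010", "BSU00030"),
    canonical = c("opuCB", "dnaE", "dnaG", "dnaN", "dnaA", "dnaX"),
    stringsAsFactors = FALSE
  )
  df$synonyms <- list(c("yvbD"), character(0), character(0),
                      c("dnaH"), character(0), c("dnaH"))
  identity_dictionary(df)
}

# three small resolved networks with a planted overlap structure
fixture_triple <- function() {
  m1 <- make_net(list("A", "B", "activation", "weak"),
                 list("A", "C", "activation", "strong"),
                 list("C", "D", "repression", "weak"))
  m2 <- make_net(list("A", "B", "repression", "strong"),
                 list("B", "E", "activation", "weak"),
                 list("E", "F", "unknown", "weak"))
  m3 <- make_net(list("C", "D", "repression", "strong"),
                 list("F", "G", "activation", "weak"),
                 list("A", "C", "dual", "weak"))
  list(m1 = m1, m2 = m2, m3 = m3)
}

expect_same_network <- function(a, b) {
  expect_equal(normalize_regnet(a), normalize_regnet(b))
}

# independent Benjamini-Hochberg step-up, kept deliberately naive
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[o][i:m] / (i:m)[seq_len(m - i + 1)], 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exhaustive-enumeration hypergeometric upper tail: fraction of all
# n-subsets of 1..N containing at least k of the first K elements
hyper_enum_oracle <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}
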