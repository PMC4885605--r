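#' Create an empty regulatory network model
#'
#' A `regnet` object is a directed graph of genes (and heteromeric
#' regulatory complexes) whose edges are transcriptional regulatory
#' interactions carrying an effect (`activation`, `repression`, `dual` or
#' `unknown`) and an evidence class (`strong`, `weak` or `unknown`).  It is
#' the common currency of the whole package: identity resolution,
#' meta-curation, global properties and the natural decomposition approach
#' all consume and produce `regnet` objects.
#'
#' @param organism Organism (strain) name the model refers to.
#' @param genome_gene_count Total number of genes in the organism's genome,
#'   used as the denominator of [genomic_coverage()].  `NA` when unknown.
#' @param metadata Named list of free-form metadata strings (e.g. sources,
#'   version).
#' @return An object of class `regnet` with empty node and edge tables.
#' @seealso [add_interactions()], [read_regnet_json()]
#' @export
#' @examples
#' net <- regnet("Bacillus subtilis 168", genome_gene_count = 4421)
#' net <- add_interactions(net, data.frame(regulator = "sigA", target = "abrB"))
#' net
regnet <- function(organism = "", genome_gene_count = NA_integer_,
                   metadata = list()) {
  if (!is.na(genome_gene_count)) {
    genome_gene_count <- as.integer(genome_gene_count)
    if (genome_gene_count <= 0L) stop("`genome_gene_count` must be positive")
  }
  structure(
    list(
      organism = as.character(organism),
      genome_gene_count = genome_gene_count,
      nodes = empty_nodes(),
      edges = empty_edges(),
      metadata = metadata
    ),
    class = "regnet"
  )
}

empty_nodes <- function() {
  df <- data.frame(
    id = character(0), canonical = character(0), locus_tag = character(0),
    kind = character(0), sigma = logical(0), rna = logical(0),
    product = character(0), class = character(0), module = character(0),
    stringsAsFactors = FALSE
  )
  df$synonyms <- list()
  df$subunits <- list()
  df
}

empty_edges <- function() {
  df <- data.frame(
    source = character(0), target = character(0),
    effect = character(0), evidence = character(0),
    stringsAsFactors = FALSE
  )
  df$sources <- list()
  df
}

#' @export
print.regnet <- function(x, ...) {
  cat(sprintf(
    "<regnet> %s\n  %d nodes (%d genes, %d complexes), %d interactions\n",
    if (nzchar(x$organism)) x$organism else "(unnamed organism)",
    nrow(x$nodes), sum(x$nodes$kind == "gene"), sum(x$nodes$kind == "complex"),
    nrow(x$edges)
  ))
  if (!is.na(x$genome_gene_count)) {
    cat(sprintf("  genome: %d genes (coverage %.1f%%)\n",
                x$genome_gene_count, genomic_coverage(x)))
  }
  if (nrow(x$edges)) {
    ev <- table(factor(x$edges$evidence, levels = .evidence_levels))
    cat(sprintf("  evidence: %d strong / %d weak / %d unknown\n",
                ev[["strong"]], ev[["weak"]], ev[["unknown"]]))
  }
  invisible(x)
}

# ---- normalisation and validation -----------------------------------------

#' Put a network into canonical order
#'
#' Sorts nodes by id and edges by (source, target) and deduplicates the
#' set-valued columns, so that two networks with identical content compare
#' equal field-for-field regardless of construction order.
#'
#' @param network A `regnet` object.
#' @return The same network in canonical order.
#' @export
normalize_regnet <- function(network) {
  stopifnot(inherits(network, "regnet"))
  n <- network$nodes
  n <- n[order(n$id), , drop = FALSE]
  n$synonyms <- lapply(n$synonyms, function(s) sort(unique(as.character(s))))
  n$subunits <- lapply(n$subunits, function(s) sort(unique(as.character(s))))
  rownames(n) <- NULL
  e <- network$edges
  e <- e[order(e$source, e$target), , drop = FALSE]
  e$sources <- lapply(e$sources, function(s) sort(unique(as.character(s))))
  rownames(e) <- NULL
  network$nodes <- n
  network$edges <- e
  if (!length(network$metadata)) network$metadata <- list()
  network
}

#' Check the internal invariants of a network model
#'
#' Verifies node-id uniqueness, that every interaction endpoint exists,
#' that complexes have at least two gene subunits, that sigma factors are
#' genes, and that effect/evidence values belong to the controlled
#' vocabularies.
#'
#' @param network A `regnet` object.
#' @return The network, invisibly; errors describe the first violation.
#' @export
validate_regnet <- function(network) {
  stopifnot(inherits(network, "regnet"))
  n <- network$nodes
  e <- network$edges
  if (anyDuplicated(n$id)) {
    stop("duplicate node ids: ", paste(unique(n$id[duplicated(n$id)]), collapse = ", "))
  }
  if (!all(n$kind %in% c("gene", "complex"))) stop("node kind must be 'gene' or 'complex'")
  bad <- setdiff(unique(c(e$source, e$target)), n$id)
  if (length(bad)) stop("interaction endpoints missing from nodes: ", paste(bad, collapse = ", "))
  if (!all(e$effect %in% .effects)) stop("invalid effect value")
  if (!all(e$evidence %in% .evidence_levels)) stop("invalid evidence value")
  cx <- n$kind == "complex"
  if (any(cx)) {
    nsub <- vapply(n$subunits[cx], length, integer(1))
    if (any(nsub < 2L)) {
      stop("complex nodes need >= 2 subunits: ", paste(n$id[cx][nsub < 2L], collapse = ", "))
    }
    # subunit ids are provenance: when a subunit is still a node in the
    # network it must be a gene (a collapse removes fully absorbed subunits)
    complex_ids <- n$id[cx]
    for (i in which(cx)) {
      bad <- intersect(n$subunits[[i]], complex_ids)
      if (length(bad)) {
        stop("complex ", n$id[i], " lists complex nodes as subunits: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  if (any(n$sigma & n$kind != "gene")) stop("sigma factors must be gene nodes")
  dup <- duplicated(paste(e$source, e$target, sep = "\r"))
  if (any(dup)) stop("duplicate interactions for pairs: ",
                     paste(paste0(e$source[dup], "->", e$target[dup]), collapse = ", "))
  invisible(network)
}

# ensure rows exist in the node table for every id in `ids`
ensure_nodes <- function(network, ids, kind = "gene") {
  new_ids <- setdiff(unique(ids), network$nodes$id)
  if (!length(new_ids)) return(network)
  add <- empty_nodes()[rep(1L, 0L), ]
  add <- data.frame(
    id = new_ids, canonical = new_ids, locus_tag = NA_character_,
    kind = kind, sigma = FALSE, rna = FALSE,
    product = NA_character_, class = NA_character_, module = NA_character_,
    stringsAsFactors = FALSE
  )
  add$synonyms <- replicate(length(new_ids), character(0), simplify = FALSE)
  add$subunits <- replicate(length(new_ids), character(0), simplify = FALSE)
  network$nodes <- rbind(network$nodes, add[names(network$nodes)])
  network
}

# ---- effect / evidence lattices -------------------------------------------

# effect lattice: unknown < {activation, repression} < dual;
# activation joined with repression is dual (conflicting reports).
effect_join <- function(a, b) {
  stopifnot(all(c(a, b) %in% .effects))
  out <- ifelse(a == b, a,
         ifelse(a == "unknown", b,
         ifelse(b == "unknown", a, "dual")))
  out
}

# evidence lattice: unknown < weak < strong (the strongest report wins)
evidence_join <- function(a, b) {
  ia <- match(a, .evidence_levels)
  ib <- match(b, .evidence_levels)
  if (anyNA(ia) || anyNA(ib)) stop("invalid evidence value")
  .evidence_levels[pmax(ia, ib)]
}

normalize_effect <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "unknown"
  sym <- c("+" = "activation", "-" = "repression", "±" = "dual",
           "+-" = "dual", "-+" = "dual", "?" = "unknown")
  hit <- x %in% names(sym)
  x[hit] <- sym[x[hit]]
  if (!all(x %in% .effects)) {
    stop("unknown effect value(s): ", paste(unique(x[!x %in% .effects]), collapse = ", "))
  }
  x
}

normalize_evidence <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "unknown"
  if (!all(x %in% .evidence_levels)) {
    stop("unknown evidence value(s): ", paste(unique(x[!x %in% .evidence_levels]), collapse = ", "))
  }
  x
}

# merge an edge table that may contain duplicate (source, target) pairs,
# folding effect/evidence through the lattices and unioning source tags
dedupe_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  key <- paste(edges$source, edges$target, sep = "\r")
  if (!anyDuplicated(key)) return(edges)
  idx <- split(seq_len(nrow(edges)), key)
  rows <- lapply(idx, function(i) {
    r <- edges[i[1L], , drop = FALSE]
    r$effect <- Reduce(effect_join, edges$effect[i])
    r$evidence <- Reduce(evidence_join, edges$evidence[i])
    r$sources <- list(sort(unique(unlist(edges$sources[i]))))
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# coerce every out-edge of a sigma-factor regulator to activation
apply_sigma_rule <- function(network) {
  sig <- network$nodes$id[network$nodes$sigma]
  if (length(sig) && nrow(network$edges)) {
    hit <- network$edges$source %in% sig
    network$edges$effect[hit] <- "activation"
  }
  network
}

#' Flag nodes as sigma factors
#'
#' Sigma factors redirect the RNA polymerase core towards specific promoter
#' sets, so their regulatory interactions are modelled as activations: all
#' current and future out-edges of a flagged node are coerced to effect
#' `activation`.
#'
#' @param network A `regnet` object.
#' @param ids Node ids to flag.
#' @return The updated network.
#' @export
set_sigma_factors <- function(network, ids) {
  stopifnot(inherits(network, "regnet"))
  miss <- setdiff(ids, network$nodes$id)
  if (length(miss)) stop("unknown node id(s): ", paste(miss, collapse = ", "))
  network$nodes$sigma[network$nodes$id %in% ids] <- TRUE
  apply_sigma_rule(network)
}

# ---- construction ----------------------------------------------------------

#' Add regulatory interactions to a network
#'
#' Ingests raw interaction records, auto-creating gene nodes for unseen
#' identifiers.  Duplicate (regulator, target) pairs -- within the new rows
#' or against existing edges -- are merged through the effect and evidence
#' lattices (`unknown < activation/repression < dual`, conflicting
#' activation/repression reports become `dual`; `unknown < weak < strong`).
#' Out-edges of sigma-factor regulators are coerced to activation.
#'
#' @param network A `regnet` object.
#' @param rows A data frame with columns `regulator` and `target`, and
#'   optionally `effect` (words or the symbols `+`, `-`, `±`, `?`),
#'   `evidence` (`strong`/`weak`/`unknown`) and `source` (provenance tag).
#' @return The updated network (idempotent: adding the same rows twice
#'   leaves the network unchanged).
#' @export
add_interactions <- function(network, rows) {
  stopifnot(inherits(network, "regnet"), is.data.frame(rows))
  if (!nrow(rows)) return(network)
  if (!all(c("regulator", "target") %in% names(rows))) {
    stop("`rows` must have columns 'regulator' and 'target'")
  }
  reg <- as.character(rows$regulator)
  tgt <- as.character(rows$target)
  bad <- which(is.na(reg) | reg == "" | is.na(tgt) | tgt == "")
  if (length(bad)) {
    stop("malformed interaction row(s) (missing regulator or target): row ",
         paste(bad, collapse = ", "))
  }
  eff <- normalize_effect(if ("effect" %in% names(rows)) rows$effect else rep("unknown", nrow(rows)))
  evd <- normalize_evidence(if ("evidence" %in% names(rows)) rows$evidence else rep("unknown", nrow(rows)))
  src <- if ("source" %in% names(rows)) as.character(rows$source) else rep(NA_character_, nrow(rows))
  network <- ensure_nodes(network, c(reg, tgt))
  add <- data.frame(source = reg, target = tgt, effect = eff, evidence = evd,
                    stringsAsFactors = FALSE)
  add$sources <- lapply(src, function(s) if (is.na(s) || s == "") character(0) else s)
  network$edges <- dedupe_edges(rbind(network$edges, add))
  network <- apply_sigma_rule(network)
  normalize_regnet(network)
}

# ---- genomic coverage ------------------------------------------------------

#' Genomic coverage of a network model
#'
#' Completeness proxy for a regulatory network model: the percentage of the
#' organism's genes present in the model.  Complex nodes are composites of
#' gene nodes that are already counted, so only gene-kind nodes enter the
#' numerator.
#'
#' @param network A `regnet` object with `genome_gene_count` set.
#' @return Coverage percentage in (0, 100].
#' @export
genomic_coverage <- function(network) {
  stopifnot(inherits(network, "regnet"))
  if (is.na(network$genome_gene_count) || network$genome_gene_count <= 0) {
    stop("genome_gene_count is not set; supply it via regnet(genome_gene_count=) ",
         "before computing genomic coverage")
  }
  100 * sum(network$nodes$kind == "gene") / network$genome_gene_count
}

# ---- projections -----------------------------------------------------------

#' Project a network onto a supported subset
#'
#' Either keeps only strongly supported interactions (edges with evidence
#' `weak` or `unknown` are dropped, then nodes left without any incident
#' edge are removed) or restricts the network to the genes of one module
#' and the interactions among them (requires [nda_decompose()] results to
#' have been applied to the node table).
#'
#' @param network A `regnet` object.
#' @param evidence `"strong"` to apply the evidence projection.
#' @param module A module id (e.g. `"1.2"`) for the module projection.
#'   Exactly one of `evidence`/`module` must be given.
#' @return The projected `regnet`.
#' @export
project_subnetwork <- function(network, evidence = NULL, module = NULL) {
  stopifnot(inherits(network, "regnet"))
  if (is.null(evidence) == is.null(module)) {
    stop("give exactly one of `evidence` or `module`")
  }
  if (!is.null(evidence)) {
    if (!identical(evidence, "strong")) stop("only the 'strong' evidence projection is defined")
    keep <- network$edges$evidence == "strong"
    network$edges <- network$edges[keep, , drop = FALSE]
    used <- unique(c(network$edges$source, network$edges$target))
    network$nodes <- network$nodes[network$nodes$id %in% used, , drop = FALSE]
  } else {
    known <- unique(network$nodes$module[!is.na(network$nodes$module)])
    if (!module %in% known) stop("unknown module id: ", module)
    ids <- network$nodes$id[!is.na(network$nodes$module) & network$nodes$module == module]
    network$nodes <- network$nodes[network$nodes$id %in% ids, , drop = FALSE]
    keep <- network$edges$source %in% ids & network$edges$target %in% ids
    network$edges <- network$edges[keep, , drop = FALSE]
  }
  normalize_regnet(network)
}

# ---- igraph bridge ---------------------------------------------------------

#' Convert a network model to an igraph object
#'
#' @param network A `regnet` object.
#' @return A directed `igraph` graph whose vertices carry the node
#'   attributes and whose edges carry effect and evidence.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "regnet"))
  v <- network$nodes[, c("id", "canonical", "kind", "sigma", "rna")]
  names(v)[1] <- "name"
  e <- network$edges[, c("source", "target", "effect", "evidence")]
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}

# out-degrees excluding self-loops, named by node id
out_degrees <- function(network) {
  e <- network$edges
  e <- e[e$source != e$target, , drop = FALSE]
  k <- table(factor(e$source, levels = network$nodes$id))
  setNames(as.integer(k), network$nodes$id)
}

in_neighbors <- function(network, id) {
  e <- network$edges
  unique(e$source[e$target == id & e$source != id])
}
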