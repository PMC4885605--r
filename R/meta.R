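#' Define an evidence-strength classification scheme
#'
#' Curated interaction evidences come in two confidence tiers: strong
#' (direct physical interaction or solid genetic evidence, e.g.
#' footprinting with purified protein or site mutation) and weak
#' (ambiguous, indirect or computational support, e.g. gel shift with cell
#' extracts, expression analysis, bioinformatic predictions).
#'
#' @param strong_codes Character vector of evidence codes counted as strong.
#' @param weak_codes Character vector of codes counted as weak (must be
#'   disjoint from `strong_codes`).
#' @return An object of class `evidence_scheme`.
#' @export
evidence_scheme <- function(strong_codes, weak_codes = character(0)) {
  strong_codes <- unique(as.character(strong_codes))
  weak_codes <- unique(as.character(weak_codes))
  clash <- intersect(strong_codes, weak_codes)
  if (length(clash)) {
    stop("codes cannot be both strong and weak: ", paste(clash, collapse = ", "))
  }
  structure(list(strong_codes = strong_codes, weak_codes = weak_codes),
            class = "evidence_scheme")
}

#' Classify the evidence supporting one interaction
#'
#' An interaction supported by at least one strong evidence code is
#' classified as strong; otherwise it is weakly supported.  An interaction
#' with no recorded evidence defaults to weak.
#'
#' @param evidences Character vector of evidence codes for one interaction.
#' @param scheme An [evidence_scheme()].
#' @return `"strong"` or `"weak"`.
#' @export
classify_evidence <- function(evidences, scheme) {
  stopifnot(inherits(scheme, "evidence_scheme"))
  evidences <- as.character(evidences)
  evidences <- evidences[!is.na(evidences) & evidences != ""]
  if (any(evidences %in% scheme$strong_codes)) "strong" else "weak"
}

#' Merge regulatory network models into a meta-curated model
#'
#' Independent curated datasets for the same organism overlap poorly, so
#' merging them yields substantially more complete models.  Nodes are
#' unioned by id and interactions by (regulator, target); conflicting
#' effects are reconciled through the effect lattice (activation joined
#' with repression becomes dual) and evidence never downgrades (the
#' strongest class wins).  Source tags are unioned.
#'
#' @param models List of `regnet` objects, all in the same (locus-tag)
#'   symbol space.
#' @param require_resolved If `TRUE`, refuse models that have not been
#'   through [collapse_synonym_nodes()] (the merge is only meaningful in
#'   locus-tag space).
#' @return The merged `regnet`.
#' @export
merge_networks <- function(models, require_resolved = FALSE) {
  stopifnot(is.list(models), length(models) >= 1L)
  lapply(models, function(m) stopifnot(inherits(m, "regnet")))
  if (require_resolved) {
    ok <- vapply(models, function(m) isTRUE(m$metadata$resolved), logical(1))
    if (!all(ok)) {
      stop("model(s) ", paste(which(!ok), collapse = ", "),
           " still use raw symbols; run resolve_symbols()/collapse_synonym_nodes() first")
    }
  }
  out <- models[[1L]]
  for (m in models[-1L]) {
    # union of nodes, merging per-node fields
    both <- intersect(out$nodes$id, m$nodes$id)
    new <- m$nodes[!m$nodes$id %in% both, , drop = FALSE]
    if (length(both)) {
      i <- match(both, out$nodes$id)
      j <- match(both, m$nodes$id)
      out$nodes$sigma[i] <- out$nodes$sigma[i] | m$nodes$sigma[j]
      out$nodes$rna[i] <- out$nodes$rna[i] | m$nodes$rna[j]
      na_prod <- is.na(out$nodes$product[i])
      out$nodes$product[i[na_prod]] <- m$nodes$product[j[na_prod]]
      na_lt <- is.na(out$nodes$locus_tag[i])
      out$nodes$locus_tag[i[na_lt]] <- m$nodes$locus_tag[j[na_lt]]
      out$nodes$synonyms[i] <- Map(function(a, b) sort(unique(c(a, b))),
                                   out$nodes$synonyms[i], m$nodes$synonyms[j])
    }
    out$nodes <- rbind(out$nodes, new)
    out$edges <- dedupe_edges(rbind(out$edges, m$edges))
    if (!nzchar(out$organism)) out$organism <- m$organism
    if (is.na(out$genome_gene_count)) out$genome_gene_count <- m$genome_gene_count
    out$metadata$sources <- sort(unique(c(out$metadata$sources, m$metadata$sources)))
    if (isTRUE(out$metadata$resolved) && !isTRUE(m$metadata$resolved)) {
      out$metadata$resolved <- NULL
    }
  }
  # class/module assignments do not survive a merge
  out$nodes$class <- NA_character_
  out$nodes$module <- NA_character_
  normalize_regnet(out)
}

edge_keys <- function(network) {
  paste(network$edges$source, network$edges$target, sep = "\r")
}

#' Quantify the overlap among regulatory datasets
#'
#' Venn-style quantification of how much independently curated or inferred
#' datasets share: for every pair, the number of shared nodes and shared
#' directed interactions; for every subset of models, the number of nodes
#' and interactions found in exactly that subset (exclusive regions).
#'
#' @param models Named list of `regnet` objects (names default to `M1`,
#'   `M2`, ...).
#' @return An object of class `overlap_report` with data frames `pairwise`,
#'   `node_regions` and `edge_regions`.
#' @export
overlap_stats <- function(models) {
  stopifnot(is.list(models), length(models) >= 1L)
  nm <- names(models) %||% sprintf("M%d", seq_along(models))
  if (is.null(names(models)) || any(!nzchar(nm))) nm <- sprintf("M%d", seq_along(models))
  node_sets <- lapply(models, function(m) m$nodes$id)
  edge_sets <- lapply(models, edge_keys)

  pairs <- if (length(models) >= 2L) utils::combn(seq_along(models), 2L) else matrix(integer(0), 2L, 0L)
  pairwise <- data.frame(
    a = nm[pairs[1L, ]], b = nm[pairs[2L, ]],
    shared_nodes = apply(pairs, 2L, function(p) length(intersect(node_sets[[p[1L]]], node_sets[[p[2L]]]))),
    shared_edges = apply(pairs, 2L, function(p) length(intersect(edge_sets[[p[1L]]], edge_sets[[p[2L]]]))),
    stringsAsFactors = FALSE
  )

  regions <- function(sets) {
    all_items <- unique(unlist(sets))
    if (!length(all_items)) {
      return(data.frame(subset = character(0), count = integer(0), stringsAsFactors = FALSE))
    }
    member <- vapply(sets, function(s) all_items %in% s, logical(length(all_items)))
    member <- matrix(member, nrow = length(all_items))
    key <- apply(member, 1L, function(r) paste(nm[r], collapse = "&"))
    tab <- table(key)
    data.frame(subset = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(
    list(models = nm,
         sizes = data.frame(model = nm,
                            nodes = lengths(node_sets),
                            edges = lengths(edge_sets),
                            stringsAsFactors = FALSE, row.names = NULL),
         pairwise = pairwise,
         node_regions = regions(node_sets),
         edge_regions = regions(edge_sets)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d models\n", length(x$models)))
  print(x$pairwise)
  invisible(x)
}

#' Test whether one dataset is contained in another
#'
#' A dataset completely included in another carries no independent
#' information and is discarded during meta-curation.
#'
#' @param a,b `regnet` objects.
#' @return `TRUE` iff all nodes and all directed interactions of `a` occur
#'   in `b`.
#' @export
containment_check <- function(a, b) {
  stopifnot(inherits(a, "regnet"), inherits(b, "regnet"))
  all(a$nodes$id %in% b$nodes$id) && all(edge_keys(a) %in% edge_keys(b))
}

#' Filter out very small network models
#'
#' Very small datasets (mostly disconnected, tree-like regulons) are
#' excluded from an atlas; the default threshold keeps models with at
#' least 110 genes.
#'
#' @param models List of `regnet` objects.
#' @param min_genes Minimum number of gene-kind nodes to keep a model.
#' @return A list with `kept` (models), `discarded` (models) and `report`
#'   (data frame of sizes and decisions).
#' @export
filter_small_networks <- function(models, min_genes = 110L) {
  stopifnot(is.list(models))
  nm <- names(models) %||% sprintf("M%d", seq_along(models))
  if (is.null(names(models)) || any(!nzchar(nm))) nm <- sprintf("M%d", seq_along(models))
  n_genes <- vapply(models, function(m) sum(m$nodes$kind == "gene"), integer(1))
  keep <- n_genes >= min_genes
  list(
    kept = models[keep],
    discarded = models[!keep],
    report = data.frame(model = nm, n_genes = n_genes, kept = keep,
                        stringsAsFactors = FALSE, row.names = NULL)
  )
}
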