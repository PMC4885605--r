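#' Build a GO annotation set
#'
#' Holds gene-to-term assignments for functional enrichment.  Only terms
#' in the `biological_process` namespace are used by [annotate_modules()],
#' because they reflect physiological processes; other namespaces are kept
#' for display.
#'
#' @param df Data frame with columns `gene` and `term`, optionally
#'   `namespace` (defaults to `biological_process`) and `term_name`.
#' @return An object of class `go_annotation_set` with elements `mapping`
#'   (named list gene -> term ids), `term_namespace` and `term_name`
#'   (named character vectors).
#' @export
go_annotation_set <- function(df) {
  stopifnot(is.data.frame(df))
  if (!nrow(df)) {
    return(structure(list(mapping = list(),
                          term_namespace = setNames(character(0), character(0)),
                          term_name = setNames(character(0), character(0))),
                     class = "go_annotation_set"))
  }
  if (!all(c("gene", "term") %in% names(df))) {
    stop("`df` needs columns gene and term")
  }
  ns <- as.character(df$namespace %||% rep("biological_process", nrow(df)))
  ns[is.na(ns) | ns == ""] <- "biological_process"
  tn <- as.character(df$term_name %||% rep(NA_character_, nrow(df)))
  gene <- as.character(df$gene)
  term <- as.character(df$term)
  mapping <- lapply(split(term, gene), function(x) sort(unique(x)))
  first <- !duplicated(term)
  term_namespace <- setNames(ns[first], term[first])
  term_name <- setNames(tn[first], term[first])
  term_name <- term_name[!is.na(term_name)]
  structure(list(mapping = mapping, term_namespace = term_namespace,
                 term_name = term_name),
            class = "go_annotation_set")
}

#' @export
print.go_annotation_set <- function(x, ...) {
  cat(sprintf("<go_annotation_set> %d genes, %d terms (%d biological_process)\n",
              length(x$mapping), length(x$term_namespace),
              sum(x$term_namespace == "biological_process")))
  invisible(x)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability that a module of size `n` drawn without
#' replacement from a background of `N` genes, `K` of which carry the
#' term, contains at least the observed `k` term-carrying genes:
#' `P(X >= k)` under the hypergeometric distribution.
#'
#' @param module_genes Character vector of module gene ids (non-empty,
#'   must be a subset of the background).
#' @param background_genes Character vector, the gene universe.
#' @param term_genes Character vector of genes annotated with the term
#'   (genes outside the background are ignored).
#' @return The p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(module_genes, background_genes, term_genes) {
  module_genes <- unique(as.character(module_genes))
  background_genes <- unique(as.character(background_genes))
  if (!length(module_genes)) stop("empty module")
  if (!length(background_genes)) stop("empty background")
  out <- setdiff(module_genes, background_genes)
  if (length(out)) {
    stop("module genes missing from background: ", paste(head(out, 5L), collapse = ", "))
  }
  term_genes <- intersect(unique(as.character(term_genes)), background_genes)
  N <- length(background_genes)
  K <- length(term_genes)
  n <- length(module_genes)
  k <- length(intersect(term_genes, module_genes))
  # P(X >= k); phyper gives P(X <= q), so query q = k - 1 on the upper tail
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up control of the false discovery rate: with `m` ordered p-values,
#' `q_(i) = min_(j >= i) m * p_(j) / j`, capped at 1, returned in the
#' original order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Annotate modules by GO biological-process enrichment
#'
#' For each module, every biological-process term annotating at least one
#' module gene is tested with [hypergeom_pvalue()] against the background;
#' p-values are corrected to q-values per module (the family of tests is
#' the terms tested within that module) and results at `q <= alpha` are
#' reported.
#'
#' @param partition Named list module id -> gene ids, or an
#'   [nda_decompose()] result.
#' @param annotations A [go_annotation_set()].
#' @param alpha Reporting FDR level (default 0.05).
#' @param background Gene universe; defaults to the union of partition
#'   genes and annotated genes.
#' @param all_results If `TRUE`, return every tested term regardless of q.
#' @return Data frame with columns `module`, `term`, `term_name`, `k`
#'   (module genes with the term), `n` (module size), `K` (background
#'   genes with the term), `N`, `p_value`, `q_value`.
#' @export
annotate_modules <- function(partition, annotations, alpha = 0.05,
                             background = NULL, all_results = FALSE) {
  if (inherits(partition, "nda_decomposition")) partition <- partition$partition
  stopifnot(is.list(partition), inherits(annotations, "go_annotation_set"))
  empty <- data.frame(module = character(0), term = character(0),
                      term_name = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(partition)) return(empty)
  bp_terms <- names(annotations$term_namespace)[
    annotations$term_namespace == "biological_process"]
  if (!length(bp_terms)) {
    warning("no biological_process annotations available; nothing to test")
    return(empty)
  }
  mapping <- lapply(annotations$mapping, function(t) intersect(t, bp_terms))
  background <- unique(as.character(
    background %||% c(unlist(partition), names(annotations$mapping))))
  genes_of_term <- split(
    rep(names(mapping), lengths(mapping)), unlist(mapping))

  out <- lapply(names(partition), function(mod) {
    genes <- intersect(partition[[mod]], background)
    if (!length(genes)) return(NULL)
    terms <- sort(unique(unlist(mapping[intersect(genes, names(mapping))])))
    if (!length(terms)) return(NULL)
    p <- vapply(terms, function(tm) {
      hypergeom_pvalue(genes, background, genes_of_term[[tm]])
    }, numeric(1))
    res <- data.frame(
      module = mod, term = terms,
      term_name = unname(annotations$term_name[terms]),
      k = vapply(terms, function(tm) length(intersect(genes_of_term[[tm]], genes)), integer(1)),
      n = length(genes),
      K = vapply(terms, function(tm) length(intersect(genes_of_term[[tm]], background)), integer(1)),
      N = length(background),
      p_value = unname(p),
      q_value = unname(bh_fdr(p)),
      stringsAsFactors = FALSE
    )
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  if (!all_results) out <- out[out$q_value <= alpha, , drop = FALSE]
  out <- out[order(out$module, out$q_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Guilt-by-association candidates
#'
#' If a gene belongs to a system enriched for a function, the gene is a
#' candidate for that function -- a systems-level route to annotate genes
#' whose products are hypothetical or uncharacterized.  Reports every gene
#' with a hypothetical/missing product description that belongs to a
#' module with at least one enriched term, paired with those terms.
#'
#' @param enrichment An [annotate_modules()] result.
#' @param partition Named list module id -> gene ids, or an
#'   [nda_decompose()] result.
#' @param products Named character vector gene id -> product description
#'   (`NA`, empty, or matching hypothetical/uncharacterized/unknown marks
#'   a candidate).
#' @return Data frame with columns `gene`, `module`, `product`, `terms`
#'   (semicolon-separated enriched term ids) and `min_q`.
#' @export
guilt_by_association <- function(enrichment, partition, products) {
  if (inherits(partition, "nda_decomposition")) partition <- partition$partition
  stopifnot(is.data.frame(enrichment), is.list(partition))
  empty <- data.frame(gene = character(0), module = character(0),
                      product = character(0), terms = character(0),
                      min_q = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(enrichment)) return(empty)
  is_hypothetical <- function(p) {
    is.na(p) | p == "" | grepl("hypothetical|uncharacterized|unknown", p,
                               ignore.case = TRUE)
  }
  out <- lapply(unique(enrichment$module), function(mod) {
    genes <- partition[[mod]]
    if (is.null(genes)) return(NULL)
    prod <- products[genes]
    names(prod) <- genes
    cand <- genes[is_hypothetical(unname(prod[genes]))]
    if (!length(cand)) return(NULL)
    rows <- enrichment[enrichment$module == mod, , drop = FALSE]
    data.frame(
      gene = cand, module = mod,
      product = unname(prod[cand]),
      terms = paste(rows$term, collapse = ";"),
      min_q = min(rows$q_value),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$module, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
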