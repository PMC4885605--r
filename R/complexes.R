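#' Collapse heteromeric regulatory complexes
#'
#' Curated regulatory datasets are gene-based, so the genes encoding the
#' subunits of a heteromeric regulatory complex each appear to regulate the
#' complex's targets, duplicating interactions.  Given curated complex
#' definitions this function removes that redundancy:
#'
#' * if all subunit genes are regulated by the same set of regulators and
#'   none exhibits regulatory activity independent of the complex, the
#'   subunit nodes are replaced by a single complex node that inherits the
#'   shared in-edges and carries the complex's out-edges;
#' * otherwise the complex is added as a new node activated by each
#'   subunit-encoding gene; out-edges mediated by the complex are moved to
#'   it, while out-edges of independently acting subunits stay on the
#'   subunit.
#'
#' @param network A `regnet` object.
#' @param complex_defs A data frame with columns `complex_id`, `subunits`
#'   and `targets`; the latter two either list-columns of character
#'   vectors or pipe-separated strings (`"a|b"`).  `targets` is the set of
#'   genes whose regulation is mediated by the complex.
#' @return The updated network; duplicate edges produced by the collapse
#'   are merged through the effect/evidence lattices.
#' @export
collapse_complexes <- function(network, complex_defs) {
  stopifnot(inherits(network, "regnet"))
  if (is.null(complex_defs) || !nrow(complex_defs)) return(network)
  if (!all(c("complex_id", "subunits", "targets") %in% names(complex_defs))) {
    stop("`complex_defs` needs columns complex_id, subunits, targets")
  }
  split_col <- function(x) {
    if (is.list(x)) lapply(x, as.character)
    else strsplit(ifelse(is.na(x), "", as.character(x)), "|", fixed = TRUE)
  }
  subs_l <- split_col(complex_defs$subunits)
  tgts_l <- split_col(complex_defs$targets)

  for (i in seq_len(nrow(complex_defs))) {
    cid <- as.character(complex_defs$complex_id[i])
    subs <- unique(subs_l[[i]])
    tgts <- unique(tgts_l[[i]])
    if (length(subs) < 2L) {
      stop("complex ", cid, " must have at least 2 subunits")
    }
    miss <- setdiff(subs, network$nodes$id)
    if (length(miss)) {
      stop("complex ", cid, " references unknown subunit(s): ",
           paste(miss, collapse = ", "))
    }
    e <- network$edges
    in_regs <- lapply(subs, function(s) sort(unique(e$source[e$target == s])))
    independent <- vapply(subs, function(s) {
      any(!e$target[e$source == s] %in% tgts)
    }, logical(1))
    shared_in <- all(vapply(in_regs, identical, logical(1), y = in_regs[[1L]]))

    # edges from subunits to the complex-mediated targets, reconciled
    med <- e[e$source %in% subs & e$target %in% tgts, , drop = FALSE]
    out_edges <- empty_edges()
    for (t in tgts) {
      rows <- med[med$target == t, , drop = FALSE]
      add <- data.frame(source = cid, target = t,
                        effect = if (nrow(rows)) Reduce(effect_join, rows$effect) else "unknown",
                        evidence = if (nrow(rows)) Reduce(evidence_join, rows$evidence) else "unknown",
                        stringsAsFactors = FALSE)
      add$sources <- list(sort(unique(unlist(rows$sources))))
      out_edges <- rbind(out_edges, add)
    }

    if (shared_in && !any(independent)) {
      # full collapse: complex replaces the subunit genes
      inherited <- empty_edges()
      for (r in in_regs[[1L]]) {
        rows <- e[e$source == r & e$target %in% subs, , drop = FALSE]
        add <- data.frame(source = r, target = cid,
                          effect = Reduce(effect_join, rows$effect),
                          evidence = Reduce(evidence_join, rows$evidence),
                          stringsAsFactors = FALSE)
        add$sources <- list(sort(unique(unlist(rows$sources))))
        inherited <- rbind(inherited, add)
      }
      keep <- !(e$source %in% subs | e$target %in% subs)
      network$edges <- rbind(e[keep, , drop = FALSE], inherited, out_edges)
      network$nodes <- network$nodes[!network$nodes$id %in% subs, , drop = FALSE]
    } else {
      # partial collapse: complex activated by its subunit genes
      drop <- e$source %in% subs & e$target %in% tgts
      act <- data.frame(source = subs, target = cid, effect = "activation",
                        evidence = "unknown", stringsAsFactors = FALSE)
      act$sources <- replicate(length(subs), character(0), simplify = FALSE)
      network$edges <- rbind(e[!drop, , drop = FALSE], act, out_edges)
    }
    network <- ensure_nodes(network, cid, kind = "complex")
    network$nodes$subunits[network$nodes$id == cid] <- list(sort(subs))
    network$edges <- dedupe_edges(network$edges)
  }
  validate_regnet(normalize_regnet(network))
}
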