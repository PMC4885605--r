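#' Build a gene-identity dictionary
#'
#' The dictionary is the substrate of gene-symbol disambiguation: one entry
#' per locus tag, with the canonical gene name (falling back to the locus
#' tag when no name exists) and any synonyms under which the gene appears
#' in curated datasets.
#'
#' @param entries A data frame with columns `locus_tag`, `canonical`,
#'   optionally `synonyms` (list-column of character vectors or
#'   pipe-separated strings), `uniprot` and `geneid`.
#' @return An object of class `identity_dictionary`.
#' @export
identity_dictionary <- function(entries) {
  stopifnot(is.data.frame(entries))
  if (!all(c("locus_tag", "canonical") %in% names(entries))) {
    stop("`entries` needs columns locus_tag and canonical")
  }
  lt <- as.character(entries$locus_tag)
  if (any(is.na(lt) | lt == "")) stop("empty locus tags are not allowed")
  if (anyDuplicated(lt)) {
    stop("duplicate locus tags: ", paste(unique(lt[duplicated(lt)]), collapse = ", "))
  }
  canon <- as.character(entries$canonical)
  canon[is.na(canon) | canon == ""] <- lt[is.na(canon) | canon == ""]
  syn <- entries$synonyms %||% replicate(length(lt), character(0), simplify = FALSE)
  if (!is.list(syn)) {
    syn <- strsplit(ifelse(is.na(syn), "", as.character(syn)), "|", fixed = TRUE)
  }
  syn <- lapply(syn, function(s) sort(unique(as.character(s[!is.na(s) & s != ""]))))
  df <- data.frame(locus_tag = lt, canonical = canon, stringsAsFactors = FALSE)
  df$synonyms <- syn
  df$uniprot <- as.character(entries$uniprot %||% rep(NA_character_, length(lt)))
  df$geneid <- as.character(entries$geneid %||% rep(NA_character_, length(lt)))
  structure(list(entries = df), class = "identity_dictionary")
}

#' @export
print.identity_dictionary <- function(x, ...) {
  cat(sprintf("<identity_dictionary> %d locus tags, %d synonyms\n",
              nrow(x$entries), sum(lengths(x$entries$synonyms))))
  invisible(x)
}

#' Build the name/locus-tag bipartite graph
#'
#' Models the equivalence relations between locus tags and gene names as a
#' bipartite graph: each dictionary entry contributes one canonical link
#' (name to locus tag) and one synonym link per synonym.  The degree of a
#' name node is the number of locus tags that name can denote; degree
#' greater than one is the degeneracy that makes a name ambiguous.
#'
#' @param dictionary An [identity_dictionary()].
#' @return An object of class `name_bipartite` with elements `name_nodes`,
#'   `locus_nodes` and `links` (data frame `name`, `locus_tag`, `kind`).
#' @export
build_bipartite <- function(dictionary) {
  stopifnot(inherits(dictionary, "identity_dictionary"))
  df <- dictionary$entries
  links <- empty_links()
  if (nrow(df)) {
    has_name <- df$canonical != df$locus_tag
    canon <- data.frame(name = df$canonical[has_name],
                        locus_tag = df$locus_tag[has_name],
                        kind = rep("canonical", sum(has_name)),
                        stringsAsFactors = FALSE)
    nsyn <- lengths(df$synonyms)
    syn <- data.frame(name = as.character(unlist(df$synonyms)),
                      locus_tag = rep(df$locus_tag, nsyn),
                      kind = rep("synonym", sum(nsyn)),
                      stringsAsFactors = FALSE)
    links <- rbind(canon, syn)
    links <- unique(links)
    links <- links[order(links$name, links$locus_tag, links$kind), , drop = FALSE]
    rownames(links) <- NULL
  }
  structure(
    list(
      name_nodes = sort(unique(links$name)),
      locus_nodes = sort(df$locus_tag),
      links = links,
      canonical_of = setNames(df$canonical, df$locus_tag)
    ),
    class = "name_bipartite"
  )
}

empty_links <- function() {
  data.frame(name = character(0), locus_tag = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.name_bipartite <- function(x, ...) {
  cat(sprintf("<name_bipartite> %d names, %d locus tags, %d links\n",
              length(x$name_nodes), length(x$locus_nodes), nrow(x$links)))
  invisible(x)
}

#' Resolve gene symbols onto locus tags
#'
#' Constrained mapping of arbitrary gene symbols onto unambiguous locus
#' tags.  A symbol equal to a locus tag maps to itself (locus tags are the
#' unambiguous key set and win over same-spelled names); a symbol equal to
#' a unique canonical name maps through that canonical link.  Remaining
#' symbols map through the bipartite graph only when their name node has
#' degree exactly one; a degenerate name (degree > 1) is marked taboo and
#' kept verbatim for historical consistency, as is a symbol absent from
#' the dictionary.  Matching is case-sensitive; a case-insensitive retry
#' is attempted only for symbols the exact passes could not find at all.
#'
#' @param symbols Character vector of gene symbols.
#' @param graph A [build_bipartite()] result.
#' @return An object of class `symbol_resolution` with elements `mapping`
#'   (named character vector symbol -> locus tag), `taboo` (character
#'   vector), `canonical_of` (locus tag -> canonical name) and `detail`
#'   (per-symbol data frame with the resolution route).
#' @export
resolve_symbols <- function(symbols, graph) {
  stopifnot(inherits(graph, "name_bipartite"))
  symbols <- unique(as.character(symbols))
  status <- setNames(rep(NA_character_, length(symbols)), symbols)
  locus <- setNames(rep(NA_character_, length(symbols)), symbols)

  canon_links <- graph$links[graph$links$kind == "canonical", , drop = FALSE]
  resolve_one <- function(s, locus_nodes, links, canon) {
    if (s %in% locus_nodes) return(c("locus_tag", s))
    hits <- unique(canon$locus_tag[canon$name == s])
    if (length(hits) == 1L) return(c("canonical", hits))
    if (length(hits) > 1L) return(c("taboo_degenerate", NA_character_))
    deg <- unique(links$locus_tag[links$name == s])
    if (length(deg) == 1L) return(c("synonym", deg))
    if (length(deg) > 1L) return(c("taboo_degenerate", NA_character_))
    c("absent", NA_character_)
  }

  for (s in symbols) {
    r <- resolve_one(s, graph$locus_nodes, graph$links, canon_links)
    status[s] <- r[1L]
    locus[s] <- r[2L]
  }

  # case-insensitive fallback only for symbols the exact passes never saw
  pending <- names(status)[status == "absent"]
  if (length(pending)) {
    lc_links <- graph$links
    lc_links$name <- tolower(lc_links$name)
    lc_canon <- lc_links[lc_links$kind == "canonical", , drop = FALSE]
    lc_locus <- tolower(graph$locus_nodes)
    for (s in pending) {
      sl <- tolower(s)
      hit <- graph$locus_nodes[lc_locus == sl]
      if (length(hit) == 1L) {
        status[s] <- "locus_tag_ci"; locus[s] <- hit; next
      }
      if (length(hit) > 1L) { status[s] <- "taboo_degenerate"; next }
      hits <- unique(lc_canon$locus_tag[lc_canon$name == sl])
      if (length(hits) == 1L) { status[s] <- "canonical_ci"; locus[s] <- hits; next }
      if (length(hits) > 1L) { status[s] <- "taboo_degenerate"; next }
      deg <- unique(lc_links$locus_tag[lc_links$name == sl])
      if (length(deg) == 1L) { status[s] <- "synonym_ci"; locus[s] <- deg; next }
      status[s] <- if (length(deg)) "taboo_degenerate" else "taboo_unknown"
    }
  }

  resolved <- !is.na(locus)
  mapping <- locus[resolved]
  canonical_of <- graph$canonical_of[unique(mapping)]
  canonical_of <- canonical_of[!is.na(canonical_of)]
  structure(
    list(
      mapping = mapping,
      taboo = sort(names(status)[!resolved]),
      canonical_of = canonical_of,
      detail = data.frame(symbol = symbols, status = unname(status[symbols]),
                          locus_tag = unname(locus[symbols]),
                          stringsAsFactors = FALSE)
    ),
    class = "symbol_resolution"
  )
}

#' @export
print.symbol_resolution <- function(x, ...) {
  cat(sprintf("<symbol_resolution> %d resolved, %d taboo/unresolved\n",
              length(x$mapping), length(x$taboo)))
  invisible(x)
}

#' Collapse synonym nodes of a network
#'
#' Renames every resolvable node of a network to its locus tag and merges
#' nodes that turn out to denote the same gene under different symbols,
#' unioning their synonym sets and reconciling duplicated edges through
#' the effect/evidence lattices.  Taboo (unresolvable) symbols are kept as
#' their own nodes.  Canonical names are retained as node labels.
#'
#' @param network A `regnet` object whose node ids are raw gene symbols.
#' @param resolution A [resolve_symbols()] result covering the network.
#' @return The collapsed network, flagged as resolved in its metadata.
#' @export
collapse_synonym_nodes <- function(network, resolution) {
  stopifnot(inherits(network, "regnet"), inherits(resolution, "symbol_resolution"))
  map <- resolution$mapping
  old <- network$nodes$id
  is_complex <- network$nodes$kind == "complex"
  new_id <- ifelse(!is_complex & old %in% names(map), unname(map[old]), old)

  groups <- split(seq_along(old), new_id)
  rows <- lapply(names(groups), function(id) {
    i <- groups[[id]]
    n <- network$nodes[i, , drop = FALSE]
    canon <- resolution$canonical_of[id]
    if (is.na(canon) || is.null(canon)) canon <- n$canonical[1L]
    syns <- unique(c(unlist(n$synonyms), setdiff(c(n$id, n$canonical), c(id, canon))))
    df <- data.frame(
      id = id,
      canonical = unname(canon),
      locus_tag = if (id %in% unname(map) || id %in% names(resolution$canonical_of)) id else n$locus_tag[1L],
      kind = n$kind[1L],
      sigma = any(n$sigma),
      rna = any(n$rna),
      product = if (all(is.na(n$product))) NA_character_ else n$product[!is.na(n$product)][1L],
      class = NA_character_,
      module = NA_character_,
      stringsAsFactors = FALSE
    )
    df$synonyms <- list(sort(syns))
    df$subunits <- list(sort(unique(unlist(n$subunits))))
    df
  })
  network$nodes <- do.call(rbind, rows)

  rename <- setNames(new_id, old)
  if (nrow(network$edges)) {
    network$edges$source <- unname(rename[network$edges$source])
    network$edges$target <- unname(rename[network$edges$target])
    network$edges <- dedupe_edges(network$edges)
  }
  network$metadata$resolved <- TRUE
  validate_regnet(normalize_regnet(network))
  normalize_regnet(network)
}
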