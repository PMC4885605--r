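#' Serialize a network model to JSON
#'
#' Writes the package's interchange dialect: a top-level object with keys
#' `metadata` (`organism`, `genome_gene_count`, `sources`, plus any extra
#' metadata entries), `nodes` and `edges`.  Node objects carry, in fixed
#' order, `id`, `canonical`, `locus_tag`, `synonyms`, `kind`, `sigma`,
#' `rna`, `product`, `subunits`, `class` and `module` (`class`/`module`
#' are `null` before [nda_decompose()] results are applied); edge objects
#' carry `source`, `target`, `effect`, `evidence` and `sources`.  The
#' document round-trips through [read_regnet_json()] field-for-field.
#'
#' @param network A `regnet` object.
#' @param path Optional file path; when given the JSON text is written
#'   there (UTF-8) and returned invisibly.
#' @return The JSON text (a character scalar).
#' @export
write_regnet_json <- function(network, path = NULL) {
  validate_regnet(network)
  network <- normalize_regnet(network)
  n <- network$nodes
  nodes <- lapply(seq_len(nrow(n)), function(i) {
    list(
      id = n$id[i],
      canonical = n$canonical[i],
      locus_tag = if (is.na(n$locus_tag[i])) NULL else n$locus_tag[i],
      synonyms = as.list(n$synonyms[[i]]),
      kind = n$kind[i],
      sigma = n$sigma[i],
      rna = n$rna[i],
      product = if (is.na(n$product[i])) NULL else n$product[i],
      subunits = as.list(n$subunits[[i]]),
      class = if (is.na(n$class[i])) NULL else n$class[i],
      module = if (is.na(n$module[i])) NULL else n$module[i]
    )
  })
  e <- network$edges
  edges <- lapply(seq_len(nrow(e)), function(i) {
    list(
      source = e$source[i], target = e$target[i],
      effect = e$effect[i], evidence = e$evidence[i],
      sources = as.list(e$sources[[i]])
    )
  })
  extra <- network$metadata
  extra$sources <- NULL
  doc <- list(
    metadata = c(
      list(
        organism = network$organism,
        genome_gene_count = if (is.na(network$genome_gene_count)) NULL else network$genome_gene_count,
        sources = as.list(as.character(network$metadata$sources %||% character(0)))
      ),
      extra
    ),
    nodes = nodes,
    edges = edges
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                          pretty = TRUE)
  txt <- as.character(txt)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(txt), con, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

json_scalar <- function(x, path, type = "character", required = TRUE, default = NULL) {
  if (is.null(x)) {
    if (required) stop("missing required value at ", path)
    return(default)
  }
  if (length(x) != 1L) stop("expected a scalar at ", path)
  switch(type,
    character = as.character(x),
    integer = as.integer(x),
    logical = {
      if (!is.logical(x)) stop("expected true/false at ", path)
      x
    }
  )
}

#' Read a network model from JSON
#'
#' Parses and validates a document written by [write_regnet_json()] (or an
#' equivalent producer).  Schema violations are reported with the JSON path
#' of the offending value, e.g. `$.edges[3].target`.
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A `regnet` object.
#' @export
read_regnet_json <- function(path) {
  txt <- if (length(path) == 1L && !grepl("[{\n]", path) && file.exists(path)) {
    paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    path
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!is.list(doc)) stop("invalid document at $")
  meta <- doc$metadata
  if (is.null(meta)) stop("missing required value at $.metadata")
  net <- regnet(
    organism = json_scalar(meta$organism, "$.metadata.organism", required = FALSE, default = ""),
    genome_gene_count = json_scalar(meta$genome_gene_count, "$.metadata.genome_gene_count",
                                    type = "integer", required = FALSE, default = NA_integer_)
  )
  extra <- meta[setdiff(names(meta), c("organism", "genome_gene_count", "sources"))]
  net$metadata <- extra
  srcs <- unlist(meta$sources)
  if (length(srcs)) net$metadata$sources <- as.character(srcs)

  nodes <- doc$nodes %||% list()
  edges <- doc$edges %||% list()
  if (length(nodes)) {
    rows <- lapply(seq_along(nodes), function(i) {
      nd <- nodes[[i]]
      p <- sprintf("$.nodes[%d]", i)
      id <- json_scalar(nd$id, paste0(p, ".id"))
      kind <- json_scalar(nd$kind, paste0(p, ".kind"), required = FALSE, default = "gene")
      if (!kind %in% c("gene", "complex")) stop("invalid node kind at ", paste0(p, ".kind"))
      cls <- json_scalar(nd$class, paste0(p, ".class"), required = FALSE, default = NA_character_)
      if (!is.na(cls) && !cls %in% .classes) stop("invalid class at ", paste0(p, ".class"))
      df <- data.frame(
        id = id,
        canonical = json_scalar(nd$canonical, paste0(p, ".canonical"), required = FALSE, default = id),
        locus_tag = json_scalar(nd$locus_tag, paste0(p, ".locus_tag"), required = FALSE, default = NA_character_),
        kind = kind,
        sigma = json_scalar(nd$sigma, paste0(p, ".sigma"), type = "logical", required = FALSE, default = FALSE),
        rna = json_scalar(nd$rna, paste0(p, ".rna"), type = "logical", required = FALSE, default = FALSE),
        product = json_scalar(nd$product, paste0(p, ".product"), required = FALSE, default = NA_character_),
        class = cls,
        module = json_scalar(nd$module, paste0(p, ".module"), required = FALSE, default = NA_character_),
        stringsAsFactors = FALSE
      )
      df$synonyms <- list(as.character(unlist(nd$synonyms)))
      df$subunits <- list(as.character(unlist(nd$subunits)))
      df
    })
    net$nodes <- do.call(rbind, rows)
    dup <- duplicated(net$nodes$id)
    if (any(dup)) {
      stop("duplicate node id at ", sprintf("$.nodes[%d].id", which(dup)[1L]))
    }
  }
  if (length(edges)) {
    rows <- lapply(seq_along(edges), function(i) {
      ed <- edges[[i]]
      p <- sprintf("$.edges[%d]", i)
      src <- json_scalar(ed$source, paste0(p, ".source"))
      tgt <- json_scalar(ed$target, paste0(p, ".target"))
      if (!src %in% net$nodes$id) stop("unknown node '", src, "' at ", paste0(p, ".source"))
      if (!tgt %in% net$nodes$id) stop("unknown node '", tgt, "' at ", paste0(p, ".target"))
      eff <- json_scalar(ed$effect, paste0(p, ".effect"), required = FALSE, default = "unknown")
      if (!eff %in% .effects) stop("invalid effect at ", paste0(p, ".effect"))
      evd <- json_scalar(ed$evidence, paste0(p, ".evidence"), required = FALSE, default = "unknown")
      if (!evd %in% .evidence_levels) stop("invalid evidence at ", paste0(p, ".evidence"))
      df <- data.frame(source = src, target = tgt, effect = eff, evidence = evd,
                       stringsAsFactors = FALSE)
      df$sources <- list(as.character(unlist(ed$sources)))
      df
    })
    net$edges <- do.call(rbind, rows)
    key <- paste(net$edges$source, net$edges$target, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      stop("duplicate interaction at ", sprintf("$.edges[%d]", which(dup)[1L]))
    }
  }
  validate_regnet(normalize_regnet(net))
  normalize_regnet(net)
}
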