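#' Read a regulatory edge list from TSV
#'
#' Expects a tab-separated file with a header naming at least `regulator`
#' and `target`; optional columns are `effect` (words or the symbols `+`,
#' `-`, `±`, `?`), `evidence` (either the classes `strong`/`weak`/
#' `unknown`, or free-text evidence codes separated by `;` or `|` to be
#' classified through `scheme`) and `source`.  Lines starting with `#` are
#' comments.
#'
#' @param path Path to the TSV file.
#' @param scheme Optional [evidence_scheme()] used to classify free-text
#'   evidence codes.
#' @return A data frame of interaction records suitable for
#'   [add_interactions()].
#' @export
read_edge_tsv <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("regulator", "target") %in% names(df))) {
    stop("edge list ", path, " needs columns 'regulator' and 'target'")
  }
  if (!is.null(df$evidence) && !is.null(scheme)) {
    codes <- strsplit(as.character(df$evidence), "[;|]")
    df$evidence <- vapply(codes, classify_evidence, character(1), scheme = scheme)
  }
  df
}

#' Read an identity dictionary from TSV
#'
#' Columns: `locus_tag`, `canonical`, `synonyms` (pipe-separated),
#' optionally `uniprot` and `geneid`.
#'
#' @param path Path to the TSV file.
#' @return An [identity_dictionary()].
#' @export
read_identity_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  identity_dictionary(df)
}

#' Read heteromeric complex definitions from TSV
#'
#' Columns: `complex_id`, `subunits` and `targets` (both pipe-separated).
#'
#' @param path Path to the TSV file.
#' @return A data frame for [collapse_complexes()].
#' @export
read_complex_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read an evidence classification scheme from TSV
#'
#' Two columns: `code` and `class` (`strong` or `weak`).
#'
#' @param path Path to the TSV file.
#' @return An [evidence_scheme()].
#' @export
read_evidence_scheme_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("code", "class") %in% names(df))) {
    stop("evidence scheme ", path, " needs columns 'code' and 'class'")
  }
  evidence_scheme(df$code[df$class == "strong"], df$code[df$class == "weak"])
}

#' Read GO annotations from TSV
#'
#' GAF-style minimal table: columns `gene` and `term`, optionally
#' `namespace` and `term_name`.
#'
#' @param path Path to the TSV file.
#' @return A [go_annotation_set()].
#' @export
read_go_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  go_annotation_set(read.delim(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' Write the per-gene classification table
#'
#' One row per node: id, canonical name, systems-level class, module,
#' out-degree (self-loops excluded) and local clustering coefficient.
#'
#' @param network A `regnet`.
#' @param decomposition An [nda_decompose()] result.
#' @param path Output TSV path.
#' @return The table, invisibly.
#' @export
write_classes_tsv <- function(network, decomposition, path) {
  k <- out_degrees(network)
  cc <- clustering_coefficients(network)
  df <- data.frame(
    gene = network$nodes$id,
    canonical = network$nodes$canonical,
    class = unname(decomposition$classification[network$nodes$id]),
    module = unname(decomposition$module_of[network$nodes$id]),
    k_out = unname(k[network$nodes$id]),
    clustering = unname(cc[network$nodes$id]),
    stringsAsFactors = FALSE
  )
  df$module[is.na(df$module)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
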