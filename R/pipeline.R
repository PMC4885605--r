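#' Run the full curation and decomposition pipeline
#'
#' Wires the package end to end: read edge lists, resolve gene symbols
#' against an identity dictionary, quantify dataset overlap and merge,
#' collapse regulatory complexes, compute global properties, decompose
#' with the natural decomposition approach and annotate modules by GO
#' enrichment.  Stages whose inputs are not configured are skipped; every
#' produced artifact is written under `out_dir` and summarised in
#' `summary.json`.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   any of the fields: `edges` (path or vector of paths to edge TSVs),
#'   `model` (path to a model JSON, alternative to `edges`),
#'   `dictionary`, `complexes`, `sigma_list` (one id per line),
#'   `evidence_scheme`, `go` (paths); `organism`, `genome_gene_count`;
#'   `min_genes` (default 110), `alpha` (default 0.05), `seed` (default
#'   1); `out_dir` (required).
#' @return Invisibly, a list with the final network, decomposition,
#'   enrichment table and the summary; artifacts on disk as side effect.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config needs `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  min_genes <- config$min_genes %||% 110L
  summary <- list(stages = character(0))
  note <- function(fmt, ...) message(sprintf(paste0("[regnet] ", fmt), ...))

  need_file <- function(path, what) {
    if (!file.exists(path)) stop("missing ", what, " file: ", path)
    path
  }

  finish <- function(summary, failed = FALSE) {
    path <- file.path(out_dir, if (failed) "summary.partial.json" else "summary.json")
    writeLines(as.character(jsonlite::toJSON(summary, auto_unbox = TRUE,
                                             pretty = TRUE, digits = NA)), path)
  }

  result <- tryCatch({
    scheme <- if (!is.null(config$evidence_scheme)) {
      read_evidence_scheme_tsv(need_file(config$evidence_scheme, "evidence scheme"))
    }

    # --- ingest -----------------------------------------------------------
    if (!is.null(config$model)) {
      net <- read_regnet_json(need_file(config$model, "model"))
      nets <- list(net)
    } else if (!is.null(config$edges)) {
      paths <- as.character(config$edges)
      nets <- lapply(paths, function(p) {
        rows <- read_edge_tsv(need_file(p, "edge list"), scheme = scheme)
        n <- add_interactions(regnet(organism = config$organism %||% ""), rows)
        n$metadata$sources <- basename(p)
        n
      })
      names(nets) <- basename(paths)
      note("loaded %d edge list(s): %s", length(nets),
           paste(vapply(nets, function(n) sprintf("%d edges", nrow(n$edges)), ""), collapse = ", "))
    } else {
      stop("config needs either `edges` or `model`")
    }

    # --- identity resolution ---------------------------------------------
    if (!is.null(config$dictionary)) {
      dict <- read_identity_tsv(need_file(config$dictionary, "dictionary"))
      graph <- build_bipartite(dict)
      symbols <- unique(unlist(lapply(nets, function(n) n$nodes$id)))
      res <- resolve_symbols(symbols, graph)
      nets <- lapply(nets, collapse_synonym_nodes, resolution = res)
      note("resolved %d/%d symbols (%d taboo)", length(res$mapping),
           length(symbols), length(res$taboo))
      write.table(res$detail, file.path(out_dir, "resolution.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$resolved <- length(res$mapping)
      summary$taboo <- length(res$taboo)
      summary$stages <- c(summary$stages, "resolve")
    }

    # --- overlap + merge --------------------------------------------------
    if (length(nets) > 1L) {
      ov <- overlap_stats(nets)
      write.table(ov$pairwise, file.path(out_dir, "overlap.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      net <- merge_networks(nets)
      note("merged %d models: %d nodes, %d edges", length(nets),
           nrow(net$nodes), nrow(net$edges))
      summary$stages <- c(summary$stages, "merge")
    } else {
      net <- nets[[1L]]
    }

    # --- complexes, sigma factors, metadata ------------------------------
    if (!is.null(config$complexes)) {
      defs <- read_complex_tsv(need_file(config$complexes, "complex definitions"))
      net <- collapse_complexes(net, defs)
      summary$stages <- c(summary$stages, "complexes")
    }
    if (!is.null(config$sigma_list)) {
      sig <- readLines(need_file(config$sigma_list, "sigma factor list"))
      sig <- trimws(sig[nzchar(trimws(sig))])
      sig <- intersect(sig, net$nodes$id)
      if (length(sig)) net <- set_sigma_factors(net, sig)
    }
    if (!is.null(config$organism)) net$organism <- config$organism
    if (!is.null(config$genome_gene_count)) {
      net$genome_gene_count <- as.integer(config$genome_gene_count)
    }
    n_genes <- sum(net$nodes$kind == "gene")
    if (n_genes < min_genes) {
      note("model has %d genes (< %d): below the atlas inclusion threshold",
           n_genes, min_genes)
      summary$below_min_genes <- TRUE
    }
    write_regnet_json(net, file.path(out_dir, "model.json"))
    summary$n_nodes <- nrow(net$nodes)
    summary$n_edges <- nrow(net$edges)
    if (!is.na(net$genome_gene_count)) {
      summary$genomic_coverage <- genomic_coverage(net)
    }
    summary$stages <- c(summary$stages, "model")

    # --- global properties -----------------------------------------------
    props <- global_properties(net)
    fit_info <- function(f) {
      if (is.null(f)) NULL else list(a = f$a, b = f$b, n_points = f$n_points,
                                     method = f$method, converged = f$converged)
    }
    writeLines(as.character(jsonlite::toJSON(list(
      n_nodes = props$n_nodes, n_edges = props$n_edges,
      mean_degree = props$mean_degree,
      mean_clustering = mean(props$clustering),
      fit_degree = fit_info(props$fit_degree),
      fit_out_degree = fit_info(props$fit_out_degree),
      fit_clustering = fit_info(props$fit_clustering)
    ), auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")),
    file.path(out_dir, "properties.json"))
    summary$stages <- c(summary$stages, "properties")

    # --- decomposition ----------------------------------------------------
    decomp <- nda_decompose(net)
    net <- apply_decomposition(net, decomp)
    write_regnet_json(net, file.path(out_dir, "decomposed.json"))
    write_classes_tsv(net, decomp, file.path(out_dir, "classes.tsv"))
    class_counts <- table(factor(decomp$classification, levels = .classes))
    note("kappa %.3g; %d global regulators, %d modules, %d modular, %d basal, %d intermodular",
         if (is.null(decomp$kappa)) NA_real_ else decomp$kappa$kappa,
         class_counts[["global_regulator"]], length(decomp$partition),
         class_counts[["modular"]], class_counts[["basal_machinery"]],
         class_counts[["intermodular"]])
    if (!is.null(decomp$kappa)) summary$kappa <- decomp$kappa$kappa
    summary$classes <- as.list(class_counts)
    summary$n_modules <- length(decomp$partition)
    summary$stages <- c(summary$stages, "decompose")

    # --- module annotation ------------------------------------------------
    enrichment <- NULL
    if (!is.null(config$go)) {
      annotations <- read_go_tsv(need_file(config$go, "GO annotation"))
      enrichment <- annotate_modules(decomp, annotations, alpha = alpha,
                                     background = net$nodes$id[net$nodes$kind == "gene"])
      write.table(enrichment, file.path(out_dir, "modules.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("enriched terms: %d over %d modules", nrow(enrichment),
           length(unique(enrichment$module)))
      summary$enriched_terms <- nrow(enrichment)
      summary$enriched_modules <- length(unique(enrichment$module))
      summary$stages <- c(summary$stages, "annotate")
    }

    finish(summary)
    list(network = net, decomposition = decomp, enrichment = enrichment,
         summary = summary)
  }, error = function(e) {
    summary$error <- conditionMessage(e)
    finish(summary, failed = TRUE)
    stop(e)
  })
  invisible(result)
}

#' Write the synthetic fixture bundle to disk
#'
#' Materialises a planted benchmark as the plain-text inputs the pipeline
#' consumes: `edges.tsv`, `dictionary.tsv`, `go.tsv` and `truth.json`
#' (ground-truth classes and modules).
#'
#' @param dir Output directory (created if needed).
#' @param spec A [planted_network_spec()].
#' @return Invisibly, the [generate_planted_network()] result.
#' @export
write_fixture_bundle <- function(dir, spec = planted_network_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  planted <- generate_planted_network(spec)
  net <- planted$network
  e <- net$edges
  edges <- data.frame(regulator = e$source, target = e$target,
                      effect = e$effect, evidence = e$evidence,
                      source = vapply(e$sources, function(s) paste(s, collapse = "|"), ""),
                      stringsAsFactors = FALSE)
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dict <- data.frame(locus_tag = net$nodes$id, canonical = net$nodes$canonical,
                     synonyms = "", stringsAsFactors = FALSE)
  write.table(dict, file.path(dir, "dictionary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  go <- generate_go_annotations(planted$partition, seed = spec$seed)
  map <- go$annotations$mapping
  go_df <- data.frame(gene = rep(names(map), lengths(map)),
                      term = unlist(map), namespace = "biological_process",
                      stringsAsFactors = FALSE)
  write.table(go_df, file.path(dir, "go.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(as.character(jsonlite::toJSON(list(
    classification = as.list(planted$classification),
    partition = planted$partition
  ), auto_unbox = TRUE, pretty = TRUE, digits = NA)), file.path(dir, "truth.json"))
  invisible(planted)
}
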