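#' Specification for a planted benchmark network
#'
#' Describes a synthetic regulatory network with known ground truth,
#' emulating the architecture the natural decomposition approach targets:
#' a hub tier of global regulators coordinating several locally autonomous
#' modules, a basal machinery regulated only by the hubs, and intermodular
#' genes wired to regulators of two modules.  Within each module the
#' transcription factors form a regulatory tree (triangle-free, so their
#' clustering is zero), while the hubs share targets and regulate each
#' other, giving them distinct out-degrees with positive, decaying
#' clustering; the fitted clustering-versus-out-degree curve is therefore
#' anchored at the hub tier and the kappa threshold falls strictly between
#' module-TF and hub out-degrees.  The generator verifies this separation
#' and fails loudly if the requested counts break it.
#'
#' @param n_modules Number of modules.
#' @param genes_per_module Genes per module (transcription factors plus
#'   structural genes).
#' @param tfs_per_module Transcription factors per module, arranged as a
#'   binary regulatory tree.
#' @param n_global_regulators Number of hub regulators.
#' @param gr_targets_per_module Minimum number of structural genes each hub
#'   regulates in every module (hubs get staggered extras so their
#'   out-degrees are distinct).
#' @param n_basal Number of basal-machinery genes (regulated by every hub).
#' @param n_intermodular Number of intermodular genes (each regulated by
#'   one TF from each of two different modules).
#' @param edge_noise_rate Fraction of extra random within-module edges to
#'   add, in `[0, 1)`; noise pairs that would close a triangle are
#'   rejected so the planted clustering signature is preserved.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `planted_network_spec`.
#' @export
planted_network_spec <- function(n_modules = 5L, genes_per_module = 20L,
                                 tfs_per_module = 10L,
                                 n_global_regulators = 3L,
                                 gr_targets_per_module = 6L,
                                 n_basal = 10L, n_intermodular = 6L,
                                 edge_noise_rate = 0, seed = 1L) {
  spec <- list(
    n_modules = as.integer(n_modules),
    genes_per_module = as.integer(genes_per_module),
    tfs_per_module = as.integer(tfs_per_module),
    n_global_regulators = as.integer(n_global_regulators),
    gr_targets_per_module = as.integer(gr_targets_per_module),
    n_basal = as.integer(n_basal),
    n_intermodular = as.integer(n_intermodular),
    edge_noise_rate = as.numeric(edge_noise_rate),
    seed = as.integer(seed)
  )
  counts <- unlist(spec[c("n_modules", "genes_per_module", "tfs_per_module",
                          "n_global_regulators", "gr_targets_per_module",
                          "n_basal", "n_intermodular")])
  if (any(counts < 0L)) stop("all counts must be >= 0")
  if (spec$n_modules < 1L) stop("need at least one module")
  if (spec$tfs_per_module < 1L || spec$tfs_per_module > spec$genes_per_module) {
    stop("tfs_per_module must be in [1, genes_per_module]")
  }
  if (spec$n_intermodular > 0L && spec$tfs_per_module == 0L) {
    stop("intermodular genes require module transcription factors")
  }
  if (spec$n_intermodular > 0L && spec$n_modules < 2L) {
    stop("intermodular genes require at least two modules")
  }
  if (spec$edge_noise_rate < 0 || spec$edge_noise_rate >= 1) {
    stop("edge_noise_rate must be in [0, 1)")
  }
  n_struct <- spec$genes_per_module - spec$tfs_per_module
  s_max <- spec$gr_targets_per_module + 2L * (spec$n_global_regulators - 1L)
  if (spec$n_global_regulators > 0L && s_max > n_struct) {
    stop("not enough structural genes per module for the hub target sets: ",
         "need >= ", s_max, ", have ", n_struct)
  }
  structure(spec, class = "planted_network_spec")
}

#' Generate a planted benchmark network with ground truth
#'
#' Builds the network described by a [planted_network_spec()] together
#' with its ground-truth systems-level classification and module
#' partition.  One hub is flagged as a sigma factor (so its out-edges are
#' activations); evidence classes are mixed deterministically so evidence
#' projections are exercised.
#'
#' @param spec A [planted_network_spec()].
#' @return A list with elements `network` (a `regnet`), `classification`
#'   (named character vector), `partition` (named list, labelled with the
#'   ids [nda_decompose()] assigns), `module_of`, and `spec`.
#' @export
generate_planted_network <- function(spec = planted_network_spec()) {
  stopifnot(inherits(spec, "planted_network_spec"))
  with_seed(spec$seed, generate_planted_network_impl(spec))
}

generate_planted_network_impl <- function(spec) {
  M <- spec$n_modules; G <- spec$genes_per_module; T <- spec$tfs_per_module
  R <- spec$n_global_regulators
  n_struct <- G - T

  tf_id <- function(m, j) sprintf("M%dTF%02d", m, j)
  gene_id <- function(m, i) sprintf("M%dG%02d", m, i)
  rows <- list()
  add_row <- function(reg, tgt, effect, evidence, src) {
    rows[[length(rows) + 1L]] <<- data.frame(
      regulator = reg, target = tgt, effect = effect, evidence = evidence,
      source = src, stringsAsFactors = FALSE)
  }

  modules <- vector("list", M)
  for (m in seq_len(M)) {
    tfs <- if (T > 0L) tf_id(m, seq_len(T)) else character(0)
    genes <- if (n_struct > 0L) gene_id(m, seq_len(n_struct)) else character(0)
    modules[[m]] <- list(tfs = tfs, genes = genes)
    # binary regulatory tree over the TFs
    for (j in seq_len(T)[-1L]) {
      add_row(tfs[j %/% 2L], tfs[j],
              if ((m + j) %% 2L == 0L) "activation" else "repression",
              "strong", "planted")
    }
    # structural genes hang off the TFs without any TF children
    leaf_tfs <- if (T > 1L) tfs[seq_len(T) > T %/% 2L] else tfs
    for (i in seq_along(genes)) {
      parent <- leaf_tfs[(i - 1L) %% length(leaf_tfs) + 1L]
      add_row(parent, genes[i],
              if ((m + i) %% 2L == 0L) "activation" else "repression",
              "strong", "planted")
    }
  }

  # hub tier: staggered, nested target samples give distinct out-degrees
  # and positive, decaying clustering
  grs <- if (R > 0L) sprintf("GR%d", seq_len(R)) else character(0)
  if (R > 0L) {
    for (i in seq_len(R)) {
      if (i < R) for (j in seq((i + 1L), R)) {
        add_row(grs[i], grs[j], "activation", "strong", "planted")
      }
    }
    s_sizes <- spec$gr_targets_per_module + 2L * (R - seq_len(R))
    for (m in seq_len(M)) {
      pool <- sample(modules[[m]]$genes)   # one nested ordering per module
      for (i in seq_len(R)) {
        for (g in pool[seq_len(s_sizes[i])]) {
          add_row(grs[i], g, "activation",
                  if ((i + match(g, pool)) %% 3L == 0L) "weak" else "strong",
                  "planted")
        }
      }
    }
  }

  basal <- if (spec$n_basal > 0L) sprintf("B%02d", seq_len(spec$n_basal)) else character(0)
  for (b in basal) for (g in grs) add_row(g, b, "activation", "strong", "planted")

  inter <- if (spec$n_intermodular > 0L) sprintf("X%02d", seq_len(spec$n_intermodular)) else character(0)
  for (i in seq_along(inter)) {
    m1 <- (i - 1L) %% M + 1L
    m2 <- i %% M + 1L
    pick_tf <- function(m) {
      tfs <- modules[[m]]$tfs
      tfs[(i - 1L) %% length(tfs) + 1L]
    }
    add_row(pick_tf(m1), inter[i], "activation", "strong", "planted")
    add_row(pick_tf(m2), inter[i], "activation", "strong", "planted")
  }

  edges <- do.call(rbind, rows)
  net <- regnet(
    organism = "planted benchmark",
    genome_gene_count = NA_integer_,
    metadata = list(sources = "planted-generator")
  )
  net <- add_interactions(net, edges)
  all_ids <- net$nodes$id
  net$genome_gene_count <- length(all_ids)
  if (R > 0L) net <- set_sigma_factors(net, grs[1L])
  net$nodes$product <- ifelse(
    net$nodes$id %in% unlist(lapply(modules, `[[`, "genes")) &
      seq_len(nrow(net$nodes)) %% 7L == 0L,
    "hypothetical protein", "planted product")

  # within-module noise, rejecting pairs that would close a triangle
  if (spec$edge_noise_rate > 0) {
    n_noise <- round(spec$edge_noise_rate * nrow(net$edges))
    net <- add_planted_noise(net, modules, n_noise)
  }

  # ground truth
  classification <- setNames(rep("modular", length(all_ids)), all_ids)
  classification[grs] <- "global_regulator"
  classification[basal] <- "basal_machinery"
  classification[inter] <- "intermodular"

  member_sets <- lapply(modules, function(m) sort(c(m$tfs, m$genes)))
  partition <- label_planted_modules(member_sets, spec)
  module_of <- setNames(character(0), character(0))
  for (lab in names(partition)) module_of[partition[[lab]]] <- lab

  # separation guarantee: kappa must fall strictly between module-TF and
  # hub out-degrees, otherwise the requested spec is unusable
  if (R > 0L) {
    k <- out_degrees(net)
    kr <- tryCatch(compute_kappa(net), error = function(e) {
      stop("planted spec breaks kappa separation: ", conditionMessage(e))
    })
    max_tf <- max(k[setdiff(all_ids, grs)])
    min_gr <- min(k[grs])
    if (!(max_tf < kr$kappa && kr$kappa < min_gr)) {
      stop(sprintf(
        "planted spec breaks kappa separation: max module out-degree %d, kappa %.3g, min hub out-degree %d",
        max_tf, kr$kappa, min_gr))
    }
  }

  list(network = normalize_regnet(net), classification = classification,
       partition = partition, module_of = module_of, spec = spec)
}

# module ids the decomposition will assign (largest island -> "1.k")
label_planted_modules <- function(member_sets, spec) {
  if (!length(member_sets)) return(list())
  sizes <- lengths(member_sets)
  first_id <- vapply(member_sets, function(m) m[1L], character(1))
  ord <- order(-sizes, first_id)
  labels <- character(length(member_sets))
  if (spec$n_intermodular > 0L && spec$n_modules > 1L) {
    # intermodular genes chain every module into one island
    labels[ord] <- paste0("1.", seq_along(ord))
  } else {
    labels[ord[1L]] <- "1.1"
    if (length(ord) > 1L) labels[ord[-1L]] <- as.character(seq_along(ord[-1L]) + 1L)
  }
  setNames(member_sets, labels)[labels[ord]]
}

add_planted_noise <- function(net, modules, n_noise) {
  if (n_noise < 1L) return(net)
  # undirected adjacency for the triangle test
  adj <- new.env(parent = emptyenv())
  link <- function(a, b) {
    assign(a, union(get0(a, envir = adj, ifnotfound = character(0)), b), envir = adj)
    assign(b, union(get0(b, envir = adj, ifnotfound = character(0)), a), envir = adj)
  }
  for (i in seq_len(nrow(net$edges))) {
    if (net$edges$source[i] != net$edges$target[i]) {
      link(net$edges$source[i], net$edges$target[i])
    }
  }
  existing <- new.env(parent = emptyenv())
  for (key in paste(net$edges$source, net$edges$target, sep = "\r")) {
    assign(key, TRUE, envir = existing)
  }
  # a candidate source must not sit in any triangle once it gains
  # out-degree, or the low-degree end of the clustering curve would pick
  # up spurious positive points and destabilise kappa
  open_neighbourhood <- function(u) {
    nb <- get0(u, envir = adj, ifnotfound = character(0))
    if (length(nb) < 2L) return(TRUE)
    for (a in nb) {
      if (any(nb %in% get0(a, envir = adj, ifnotfound = character(0)))) return(FALSE)
    }
    TRUE
  }
  added <- 0L; tries <- 0L
  out_count <- new.env(parent = emptyenv())
  noise <- list()
  while (added < n_noise && tries < 1000L * n_noise) {
    tries <- tries + 1L
    m <- modules[[sample.int(length(modules), 1L)]]
    if (length(m$genes) < 1L) next
    u <- sample(m$genes, 1L)                # sources stay low-out-degree
    if (get0(u, envir = out_count, ifnotfound = 0L) >= 2L) next
    v <- sample(setdiff(c(m$tfs, m$genes), u), 1L)
    key <- paste(u, v, sep = "\r")
    if (get0(key, envir = existing, ifnotfound = FALSE)) next
    common <- intersect(get0(u, envir = adj, ifnotfound = character(0)),
                        get0(v, envir = adj, ifnotfound = character(0)))
    if (length(common)) next                # would close a triangle
    if (!open_neighbourhood(u)) next        # source already sits in a triangle
    noise[[length(noise) + 1L]] <- data.frame(
      regulator = u, target = v, effect = "activation", evidence = "weak",
      source = "noise", stringsAsFactors = FALSE)
    assign(key, TRUE, envir = existing)
    assign(u, get0(u, envir = out_count, ifnotfound = 0L) + 1L, envir = out_count)
    link(u, v)
    added <- added + 1L
  }
  if (length(noise)) net <- add_interactions(net, do.call(rbind, noise))
  net
}

#' Generate an identity dictionary with planted ambiguity
#'
#' Builds a dictionary of locus tags, canonical names and synonyms in
#' which exactly `n_degenerate` synonym names are shared between two locus
#' tags; those names are the expected taboo set of [resolve_symbols()].
#'
#' @param n_genes Number of locus tags.
#' @param n_synonyms Number of synonym names (the last `n_degenerate` of
#'   them are planted as degenerate).
#' @param n_degenerate Number of names shared by two locus tags.
#' @param seed Integer seed.
#' @return A list with `dictionary` (an [identity_dictionary()]) and
#'   `taboo` (the planted ambiguous names).
#' @export
generate_identity_dictionary <- function(n_genes, n_synonyms = 0L,
                                         n_degenerate = 0L, seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_synonyms <- as.integer(n_synonyms)
  n_degenerate <- as.integer(n_degenerate)
  if (n_degenerate > n_synonyms) stop("n_degenerate cannot exceed n_synonyms")
  if (n_degenerate > 0L && n_genes < 2L) stop("degenerate names need >= 2 genes")
  with_seed(seed, {
    loci <- sprintf("L%04d", seq_len(n_genes))
    canon <- sprintf("gen%03d", seq_len(n_genes))
    syn <- replicate(n_genes, character(0), simplify = FALSE)
    plain <- if (n_synonyms > n_degenerate) {
      sprintf("syn%03d", seq_len(n_synonyms - n_degenerate))
    } else character(0)
    for (s in plain) {
      i <- sample.int(n_genes, 1L)
      syn[[i]] <- c(syn[[i]], s)
    }
    amb <- if (n_degenerate > 0L) sprintf("amb%02d", seq_len(n_degenerate)) else character(0)
    for (s in amb) {
      ij <- sample.int(n_genes, 2L)
      syn[[ij[1L]]] <- c(syn[[ij[1L]]], s)
      syn[[ij[2L]]] <- c(syn[[ij[2L]]], s)
    }
    df <- data.frame(locus_tag = loci, canonical = canon, stringsAsFactors = FALSE)
    df$synonyms <- syn
    list(dictionary = identity_dictionary(df), taboo = amb)
  })
}

#' Generate planted GO annotations for a module partition
#'
#' Paints one unique biological-process term on a fraction of each
#' module's genes and, at a background rate, on the remaining genes of the
#' partition -- a controlled substrate for the hypergeometric enrichment
#' test.
#'
#' @param partition Named list module id -> gene ids, or an
#'   [nda_decompose()] result.
#' @param enriched_fraction Fraction of each module's genes carrying the
#'   module's term, in `[0, 1]`.
#' @param background_rate Probability that any other gene carries the
#'   term, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `annotations` (a [go_annotation_set()]) and `truth`
#'   (data frame `module`, `term`).
#' @export
generate_go_annotations <- function(partition, enriched_fraction = 0.9,
                                    background_rate = 0.05, seed = 1L) {
  if (inherits(partition, "nda_decomposition")) partition <- partition$partition
  stopifnot(is.list(partition))
  if (enriched_fraction < 0 || enriched_fraction > 1 ||
      background_rate < 0 || background_rate > 1) {
    stop("enriched_fraction and background_rate must lie in [0, 1]")
  }
  if (!length(partition)) {
    return(list(annotations = go_annotation_set(data.frame()),
                truth = data.frame(module = character(0), term = character(0),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    all_genes <- sort(unique(unlist(partition)))
    rows <- list()
    truth <- list()
    for (i in seq_along(partition)) {
      mod <- names(partition)[i]
      term <- sprintf("GO:%07d", 9000000L + i)
      genes <- partition[[mod]]
      n_in <- max(1L, round(enriched_fraction * length(genes)))
      painted <- sample(genes, n_in)
      others <- setdiff(all_genes, genes)
      bg <- others[runif(length(others)) < background_rate]
      for (g in c(painted, bg)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, term = term, namespace = "biological_process",
          term_name = sprintf("planted function %d", i),
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(module = mod, term = term,
                                                stringsAsFactors = FALSE)
    }
    list(annotations = go_annotation_set(do.call(rbind, rows)),
         truth = do.call(rbind, truth))
  })
}
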