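#' Closed-form kappa threshold of a fitted clustering curve
#'
#' For a clustering-versus-out-degree curve `C(k) = a * k^(-b)`, the kappa
#' value is the out-degree at which `dC/dk = -1`, i.e. where the loss of
#' modularity exactly balances the gain in hubness.  Solving
#' `-a*b*k^(-b-1) = -1` gives `kappa = (a*b)^(1/(b+1))`.
#'
#' @param a Positive amplitude of the fitted power law.
#' @param b Positive (decay) exponent.
#' @return The kappa threshold.
#' @export
kappa_threshold <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), all(a > 0), all(b > 0))
  (a * b)^(1 / (b + 1))
}

#' Compute the kappa threshold of a network
#'
#' In hierarchical-modular regulatory networks, modularity (clustering) is
#' inversely proportional to hubness (out-connectivity).  The kappa value
#' is the equilibrium point between the two behaviours: the out-degree at
#' which the variation of the fitted clustering curve equals the variation
#' of out-connectivity with opposite sign, `dC/dk_out = -1`.  With the
#' per-degree mean clustering curve fitted as `C(k_out) = a * k_out^(-b)`,
#' the threshold has the closed form `kappa = (a*b)^(1/(b+1))`.  Nodes with
#' out-degree above kappa are the network's global regulators.
#'
#' @param network A `regnet` object with at least three distinct
#'   out-degree values of positive mean clustering.
#' @param fit_method Passed to [robust_powerlaw_fit()].
#' @return An object of class `kappa_result` with elements `kappa`, `fit`
#'   (the fitted power law) and `points` (the curve that was fitted).
#' @export
compute_kappa <- function(network, fit_method = "huber_irls") {
  stopifnot(inherits(network, "regnet"))
  curve <- mean_clustering_by_out_degree(network)
  pts <- curve[curve$mean_c > 0, , drop = FALSE]
  if (nrow(pts) < 3L) {
    stop("cannot derive kappa: need >= 3 distinct out-degree values with ",
         "positive mean clustering, found ", nrow(pts),
         " (insufficient degree diversity)")
  }
  fit <- robust_powerlaw_fit(pts$k_out, pts$mean_c, method = fit_method)
  if (!is.finite(fit$b) || fit$b <= 0 || fit$a <= 0) {
    stop("cannot derive kappa: fitted clustering curve does not decay ",
         sprintf("(a = %.4g, b = %.4g)", fit$a, fit$b))
  }
  kappa <- kappa_threshold(fit$a, fit$b)
  structure(
    list(kappa = kappa, fit = fit, a = fit$a, b = fit$b, points = pts),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.4g from C(k_out) = %.4g * k_out^(-%.4g) (%d points)\n",
              x$kappa, x$a, x$b, x$fit$n_points))
  invisible(x)
}

#' Identify the global regulators of a network
#'
#' Global regulators are the nodes whose out-connectivity exceeds the
#' kappa threshold; their pleiotropy places them above modules, which they
#' coordinate rather than belong to.  Out-degree is counted on the
#' directed graph with self-loops excluded.
#'
#' @param network A `regnet` object.
#' @param kappa A [compute_kappa()] result or a positive number.
#' @return Sorted character vector of node ids.
#' @export
identify_global_regulators <- function(network, kappa) {
  stopifnot(inherits(network, "regnet"))
  if (inherits(kappa, "kappa_result")) kappa <- kappa$kappa
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  k <- out_degrees(network)
  sort(names(k)[k > kappa])
}

#' Decompose a network into systems and systems-level elements
#'
#' The natural decomposition approach classifies every gene of a
#' regulatory network into one of four systems-level classes and derives
#' the functional systems (modules) by controlled decomposition:
#'
#' 1. global regulators (out-degree above kappa) are removed;
#' 2. structural genes (zero out-degree, self-loops excluded) left without
#'    any remaining regulator are the basal machinery -- strictly globally
#'    regulated genes;
#' 3. the weakly connected components of the remaining regulators are the
#'    pre-modules;
#' 4. each structural gene is attached back: regulators in exactly one
#'    pre-module make it a modular gene of that module; regulators in two
#'    or more pre-modules make it an intermodular gene, integrating
#'    disparate module responses at promoter level;
#' 5. module ids mirror the island structure: components lying in the
#'    largest connected island of the regulator-free network are numbered
#'    `1.1`, `1.2`, ... by decreasing size, remaining islands `2`, `3`, ...
#'
#' Classes are mutually exclusive and exhaustive: global regulators, basal
#' machinery and intermodular genes never belong to a module.
#'
#' @param network A `regnet` object.
#' @param global_regulators Optional explicit set of global-regulator ids;
#'   computed from `kappa` when omitted.
#' @param kappa Optional [compute_kappa()] result or number; computed from
#'   the network when omitted and needed.
#' @return An object of class `nda_decomposition` with elements
#'   `classification` (named character vector over all nodes), `partition`
#'   (named list module id -> node ids), `module_of` (named vector for
#'   modular genes), `global_regulators`, and `kappa` (when computed).
#' @export
nda_decompose <- function(network, global_regulators = NULL, kappa = NULL) {
  stopifnot(inherits(network, "regnet"))
  kr <- NULL
  if (is.null(global_regulators)) {
    if (is.null(kappa)) {
      kr <- compute_kappa(network)
    } else if (inherits(kappa, "kappa_result")) {
      kr <- kappa
    }
    global_regulators <- identify_global_regulators(network, if (is.null(kr)) kappa else kr)
  } else {
    miss <- setdiff(global_regulators, network$nodes$id)
    if (length(miss)) stop("unknown global regulator id(s): ", paste(miss, collapse = ", "))
  }
  ids <- network$nodes$id
  gr <- sort(unique(global_regulators))
  k_out <- out_degrees(network)

  regulators <- setdiff(ids[k_out[ids] > 0L], gr)   # non-GR nodes with out-edges
  structural <- setdiff(ids[k_out[ids] == 0L], gr)  # zero regulatory output

  # pre-modules: weakly connected components of the regulator-induced graph
  e <- network$edges
  e <- e[e$source != e$target, , drop = FALSE]
  e_reg <- e[e$source %in% regulators & e$target %in% regulators, , drop = FALSE]
  comp_of <- setNames(rep(NA_integer_, length(ids)), ids)
  n_pre <- 0L
  if (length(regulators)) {
    gsub_ <- igraph::graph_from_data_frame(
      e_reg[, c("source", "target")], directed = TRUE,
      vertices = data.frame(name = regulators, stringsAsFactors = FALSE)
    )
    comps <- igraph::components(gsub_, mode = "weak")
    comp_of[regulators] <- as.integer(comps$membership[regulators])
    n_pre <- comps$no
  }

  classification <- setNames(rep(NA_character_, length(ids)), ids)
  classification[gr] <- "global_regulator"
  classification[regulators] <- "modular"
  member_comp <- comp_of  # component index for every node that is in a module

  for (s in structural) {
    regs <- setdiff(unique(e$source[e$target == s]), c(gr, s))
    mods <- unique(comp_of[regs])
    mods <- mods[!is.na(mods)]
    if (length(mods) == 0L) {
      classification[s] <- "basal_machinery"
    } else if (length(mods) == 1L) {
      classification[s] <- "modular"
      member_comp[s] <- mods
    } else {
      classification[s] <- "intermodular"
    }
  }

  # islands: weakly connected components after removing global regulators
  island_of <- setNames(rep(NA_integer_, length(ids)), ids)
  rest <- setdiff(ids, gr)
  if (length(rest)) {
    e_rest <- e[e$source %in% rest & e$target %in% rest, , drop = FALSE]
    g_rest <- igraph::graph_from_data_frame(
      e_rest[, c("source", "target")], directed = TRUE,
      vertices = data.frame(name = rest, stringsAsFactors = FALSE)
    )
    ic <- igraph::components(g_rest, mode = "weak")
    island_of[rest] <- as.integer(ic$membership[rest])
  }

  partition <- list()
  module_of <- setNames(character(0), character(0))
  if (n_pre > 0L) {
    members <- split(names(member_comp)[!is.na(member_comp)],
                     member_comp[!is.na(member_comp)])
    sizes <- lengths(members)
    first_id <- vapply(members, function(m) sort(m)[1L], character(1))
    # island each pre-module lives in, and the largest island
    mod_island <- vapply(members, function(m) island_of[[m[1L]]], integer(1))
    island_sizes <- table(island_of[rest])
    big_island <- as.integer(names(island_sizes)[which.max(island_sizes)])
    in_big <- mod_island == big_island
    ord <- order(-sizes, first_id)
    labels <- character(length(members))
    k1 <- 0L; k2 <- 1L
    for (i in ord) {
      if (in_big[i]) {
        k1 <- k1 + 1L
        labels[i] <- paste0("1.", k1)
      } else {
        k2 <- k2 + 1L
        labels[i] <- as.character(k2)
      }
    }
    partition <- setNames(lapply(members, sort), labels)
    partition <- partition[labels[ord]]
    for (lab in names(partition)) {
      module_of[partition[[lab]]] <- lab
    }
  }

  structure(
    list(
      classification = classification,
      partition = partition,
      module_of = module_of,
      global_regulators = gr,
      kappa = kr
    ),
    class = "nda_decomposition"
  )
}

#' @export
print.nda_decomposition <- function(x, ...) {
  tab <- table(factor(x$classification, levels = .classes))
  cat(sprintf(
    "<nda_decomposition> %d global regulators, %d modular genes in %d modules,\n  %d basal machinery, %d intermodular%s\n",
    tab[["global_regulator"]], tab[["modular"]], length(x$partition),
    tab[["basal_machinery"]], tab[["intermodular"]],
    if (!is.null(x$kappa)) sprintf(" (kappa = %.3g)", x$kappa$kappa) else ""
  ))
  invisible(x)
}

#' Write a decomposition back onto the network's node table
#'
#' Fills the `class` and `module` node fields used by the JSON dialect and
#' by [project_subnetwork()]'s module projection.
#'
#' @param network A `regnet` object.
#' @param decomposition An [nda_decompose()] result for that network.
#' @return The annotated network.
#' @export
apply_decomposition <- function(network, decomposition) {
  stopifnot(inherits(network, "regnet"), inherits(decomposition, "nda_decomposition"))
  cls <- decomposition$classification
  network$nodes$class <- unname(cls[network$nodes$id])
  mo <- decomposition$module_of
  network$nodes$module <- unname(mo[network$nodes$id])
  network
}

#' Arrange systems-level classes into the three-layer architecture
#'
#' The functional architecture is a diamond-shaped three-layer hierarchy:
#' a coordination layer of global regulators (with the basal machinery
#' attached to its output), a processing layer of locally autonomous
#' modules, and an integration layer of intermodular genes combining the
#' responses of several modules.
#'
#' @param decomposition An [nda_decompose()] result (or a bare named
#'   classification vector).
#' @return A list with elements `coordination`, `processing` (the module
#'   partition, or the modular gene set if only a classification was
#'   given), `integration` and `basal_machinery`.
#' @export
architecture_layers <- function(decomposition) {
  if (inherits(decomposition, "nda_decomposition")) {
    cls <- decomposition$classification
    processing <- decomposition$partition
  } else {
    cls <- decomposition
    processing <- sort(names(cls)[cls == "modular"])
  }
  list(
    coordination = sort(names(cls)[cls == "global_regulator"]),
    processing = processing,
    integration = sort(names(cls)[cls == "intermodular"]),
    basal_machinery = sort(names(cls)[cls == "basal_machinery"])
  )
}
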