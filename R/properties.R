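#' Local clustering coefficients
#'
#' Clustering is the modularity-side quantity of the natural decomposition
#' approach: a regulator embedded in a module has neighbours that are also
#' connected to each other, whereas a global hub touches many otherwise
#' unrelated genes.  Coefficients are computed on the undirected simple
#' projection of the network with self-loops removed; nodes with fewer
#' than two neighbours have coefficient 0.
#'
#' @param network A `regnet` object.
#' @return Named numeric vector in \[0, 1\], one value per node.
#' @export
clustering_coefficients <- function(network) {
  stopifnot(inherits(network, "regnet"))
  if (!nrow(network$nodes)) return(setNames(numeric(0), character(0)))
  g <- as_igraph(network)
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  setNames(cc, igraph::V(g)$name)[network$nodes$id]
}

#' Fit a power law to positive (x, y) points
#'
#' Fits `y = a * x^(-b)` by linear regression of log-transformed data.
#' Degree and clustering distributions of regulatory networks are commonly
#' fitted this way, but ordinary least squares is highly sensitive to the
#' outliers these sparse tails produce; the default therefore uses robust
#' regression with Huber's T M-estimator (tuning constant 1.345, iterated
#' reweighted least squares to tolerance 1e-8, at most 100 iterations).
#' On noiseless log-linear data the robust fit coincides with ordinary
#' least squares.
#'
#' @param x,y Numeric vectors; pairs with `x <= 0` or `y <= 0` are dropped
#'   (the log transform is undefined there).  At least 3 usable points are
#'   required.
#' @param method `"huber_irls"` (default) or `"ols"`.
#' @return An object of class `powerlaw_fit` with elements `a` (amplitude),
#'   `b` (exponent, positive for a decaying law), `n_points`, `method` and
#'   `converged`.
#' @export
robust_powerlaw_fit <- function(x, y, method = c("huber_irls", "ols")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("power-law fit needs at least 3 points with x > 0 and y > 0 (got ",
         length(x), ")")
  }
  lx <- log(x); ly <- log(y)
  ols <- lm(ly ~ lx)
  if (method == "ols" || sqrt(mean(ols$residuals^2)) < 1e-10) {
    # noiseless log-linear data: the M-estimate is the OLS estimate
    co <- coef(ols)
    converged <- TRUE
  } else {
    fit <- tryCatch(
      suppressWarnings(
        MASS::rlm(ly ~ lx, psi = MASS::psi.huber, k = 1.345,
                  acc = 1e-8, maxit = 100, scale.est = "MAD")),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      # perfectly collinear data defeats the MAD scale estimate; the
      # M-estimate then equals ordinary least squares anyway
      fit <- lm(ly ~ lx)
      converged <- TRUE
    } else {
      converged <- isTRUE(fit$converged)
    }
    co <- coef(fit)
  }
  structure(
    list(a = exp(unname(co[1L])), b = -unname(co[2L]),
         n_points = length(x), method = method, converged = converged,
         log_intercept = unname(co[1L]), log_slope = unname(co[2L])),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> y = %.4g * x^(-%.4g)  [%s, %d points%s]\n",
              x$a, x$b, x$method, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

# discrete probability distribution over all nodes: P(k) for k observed
degree_distribution_table <- function(k) {
  tab <- table(k)
  data.frame(k = as.integer(names(tab)),
             p = as.numeric(tab) / length(k),
             n = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean clustering per out-degree
#'
#' The curve the kappa threshold is derived from: for every distinct
#' out-degree value (self-loops excluded) present in the network, the mean
#' local clustering coefficient of the nodes with that out-degree.  Using
#' one point per degree value rather than one per node stabilises the fit.
#'
#' @param network A `regnet` object.
#' @return Data frame with columns `k_out`, `mean_c` and `n_nodes`,
#'   restricted to `k_out >= 1`.
#' @export
mean_clustering_by_out_degree <- function(network) {
  cc <- clustering_coefficients(network)
  k <- out_degrees(network)
  keep <- k >= 1L
  k <- k[keep]; cc <- cc[names(k)]
  if (!length(k)) {
    return(data.frame(k_out = integer(0), mean_c = numeric(0), n_nodes = integer(0)))
  }
  agg <- tapply(cc, k, mean)
  data.frame(k_out = as.integer(names(agg)),
             mean_c = as.numeric(agg),
             n_nodes = as.integer(table(k)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Global network properties
#'
#' Assembles the statistics reported for a network model: node and edge
#' counts, mean degree, the degree and out-degree distributions (over all
#' nodes), per-node clustering coefficients, the mean-clustering-per-
#' out-degree curve, and robust power-law fits of P(k), P(k_out) and
#' C(k_out) where enough positive points exist (zero-valued points are
#' excluded from the log-log fits).
#'
#' @param network A non-empty `regnet` object.
#' @param fit_method Passed to [robust_powerlaw_fit()].
#' @return An object of class `global_properties`.
#' @export
global_properties <- function(network, fit_method = "huber_irls") {
  stopifnot(inherits(network, "regnet"))
  if (!nrow(network$nodes)) stop("cannot compute properties of an empty network")
  g <- as_igraph(network)
  k_all <- igraph::degree(g, mode = "all", loops = FALSE)
  k_out <- out_degrees(network)
  cc <- clustering_coefficients(network)
  dd <- degree_distribution_table(k_all)
  dod <- degree_distribution_table(k_out)
  ck <- mean_clustering_by_out_degree(network)
  try_fit <- function(x, y) {
    tryCatch(robust_powerlaw_fit(x, y, method = fit_method),
             error = function(e) NULL)
  }
  structure(
    list(
      n_nodes = nrow(network$nodes),
      n_edges = nrow(network$edges),
      mean_degree = mean(k_all),
      degree_distribution = dd,
      out_degree_distribution = dod,
      clustering = cc,
      mean_clustering_by_out_degree = ck,
      fit_degree = try_fit(dd$k, dd$p),
      fit_out_degree = try_fit(dod$k, dod$p),
      fit_clustering = try_fit(ck$k_out, ck$mean_c)
    ),
    class = "global_properties"
  )
}

#' @export
print.global_properties <- function(x, ...) {
  cat(sprintf("<global_properties> %d nodes, %d edges, mean degree %.2f, mean C %.3f\n",
              x$n_nodes, x$n_edges, x$mean_degree, mean(x$clustering)))
  invisible(x)
}
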