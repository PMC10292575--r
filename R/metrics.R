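# Graph metrics: global efficiency, mean degree, connectedness screening and
# AUC summaries over the density range.

# All-pairs shortest-path lengths of a binary undirected graph. Small graphs
# use boolean matrix powers (no per-call construction overhead, which
# dominates in the serial-attack inner loop); larger ones go through igraph's
# BFS. Disconnected pairs stay Inf.
binary_distances <- function(adj) {
  n <- nrow(adj)
  if (n <= 64L) {
    a <- adj != 0
    storage.mode(a) <- "double"
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    reached <- a != 0 | diag(n) > 0
    d[a != 0] <- 1
    cur <- a
    k <- 1L
    while (any(!reached) && k < n) {
      cur <- (cur %*% a) > 0
      storage.mode(cur) <- "double"
      new <- cur > 0 & !reached
      if (!any(new)) break
      k <- k + 1L
      d[new] <- k
      reached <- reached | new
    }
    d
  } else {
    g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                             diag = FALSE)
    igraph::distances(g, algorithm = "unweighted")
  }
}

#' Global efficiency of a binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length,
#' \code{1/(N (N-1)) * sum_{i != j} 1/d_ij}, with \code{1/d_ij = 0} for
#' disconnected pairs. Ranges from 0 (edgeless) to 1 (complete); defined on
#' disconnected graphs, which node-deletion attacks necessarily produce.
#'
#' @param adj symmetric binary adjacency matrix with zero diagonal.
#' @return efficiency in \[0, 1\].
#' @export
global_efficiency <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  if (!any(adj != 0)) return(0)
  d <- binary_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean degree (wiring cost) of a binary graph
#'
#' Number of edges attached to each node, averaged over nodes:
#' \code{2 |E| / N}.
#'
#' @param adj symmetric binary adjacency matrix with zero diagonal.
#' @return average degree.
#' @export
mean_degree <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) == 0L) stop("empty graph")
  sum(adj != 0) / nrow(adj)
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  if (n <= 1L) return(TRUE)
  reached <- c(TRUE, rep(FALSE, n - 1L))
  frontier <- reached
  a <- adj != 0
  repeat {
    nxt <- (colSums(a[frontier, , drop = FALSE]) > 0) & !reached
    if (!any(nxt)) break
    reached <- reached | nxt
    frontier <- nxt
  }
  all(reached)
}

#' Smallest density at which a subject's graph is connected
#'
#' Screens the density sweep bottom-up by breadth-first search and reports
#' the smallest grid density whose graph forms a single connected component,
#' or \code{NA} ("unconnected") if none does. The cohort-wide analysis range
#' starts at the maximum of these over subjects, snapped to the grid; the
#' reference choice for a ~240-region cohort is \[0.3, 1\].
#'
#' @param stack a \code{\link{density_sweep}} result.
#' @return smallest connected grid density, or \code{NA_real_}.
#' @export
connected_density_range <- function(stack) {
  stopifnot(inherits(stack, "density_stack"), length(stack$densities) > 0)
  for (i in seq_along(stack$densities))
    if (is_connected_adj(stack$graphs[[i]])) return(stack$densities[i])
  NA_real_
}

#' Area under a metric profile over a density range
#'
#' Integrates metric values sampled on the density grid over
#' \[\code{range_lo}, \code{range_hi}\] (default 0.3-1.0). Trapezoidal rule by
#' default, exact for linear profiles on the grid; a left-rectangle rule is
#' available. The AUC is not normalized by the range width.
#'
#' @param densities increasing grid of densities.
#' @param values metric value at each grid density.
#' @param range_lo,range_hi analysis range; the grid must contain at least
#'   two points inside it.
#' @param method \code{"trapezoid"} (default) or \code{"left"}.
#' @return the AUC.
#' @export
auc_over_density <- function(densities, values, range_lo = 0.3,
                             range_hi = 1.0,
                             method = c("trapezoid", "left")) {
  method <- match.arg(method)
  stopifnot(length(densities) == length(values), range_lo < range_hi)
  keep <- densities >= range_lo - 1e-9 & densities <= range_hi + 1e-9
  d <- densities[keep]
  v <- values[keep]
  if (length(d) < 2L)
    stop("fewer than 2 grid points inside the analysis range")
  if (any(!is.finite(v))) stop("non-finite metric values in range")
  dd <- diff(d)
  if (method == "trapezoid") {
    sum(dd * (v[-1L] + v[-length(v)]) / 2)
  } else {
    sum(dd * v[-length(v)])
  }
}

#' Metric profile over the density sweep
#'
#' Evaluates a metric on every graph of the stack and summarizes it as the
#' AUC over the analysis range.
#'
#' @param stack a \code{\link{density_sweep}} result.
#' @param metric \code{"global_efficiency"}, \code{"mean_degree"}, or a
#'   function of a binary adjacency matrix.
#' @param range_lo,range_hi analysis range for the AUC (default 0.3-1.0).
#' @return object of class \code{density_profile}: data.frame
#'   (\code{density}, \code{value}) with attributes \code{metric},
#'   \code{range} and \code{auc}.
#' @export
density_profile <- function(stack, metric = "global_efficiency",
                            range_lo = 0.3, range_hi = 1.0) {
  stopifnot(inherits(stack, "density_stack"))
  if (is.character(metric)) {
    name <- match.arg(metric, c("global_efficiency", "mean_degree"))
    fn <- match.fun(name)
  } else {
    name <- deparse(substitute(metric))[1L]
    fn <- match.fun(metric)
  }
  vals <- vapply(stack$graphs, fn, numeric(1))
  out <- data.frame(density = stack$densities, value = vals)
  attr(out, "metric") <- name
  attr(out, "range") <- c(range_lo, range_hi)
  attr(out, "auc") <- auc_over_density(stack$densities, vals,
                                       range_lo, range_hi)
  class(out) <- c("density_profile", "data.frame")
  out
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Density profile of %s; AUC over [%.2g, %.2g] = %.6g\n",
              attr(x, "metric"), attr(x, "range")[1L], attr(x, "range")[2L],
              attr(x, "auc")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a density profile as CSV plus a JSON sidecar
#'
#' @param profile a \code{\link{density_profile}}.
#' @param path CSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @export
write_density_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  jsonlite::write_json(list(metric = attr(profile, "metric"),
                            range = attr(profile, "range"),
                            auc = attr(profile, "auc")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
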