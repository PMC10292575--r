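# Graph construction: strength normalization -> positive-weight masking ->
# proportional density sweep -> binarization.

#' Normalize a connectivity matrix by its total strength
#'
#' Divides all weights by the sum of absolute off-diagonal weights over the
#' upper triangle ("total connectivity strength") and returns the constant
#' for reporting as global connectivity strength. Proportional thresholding
#' is scale invariant, so this step never changes the binarized graphs; it
#' exists so the strength constant can be reported and compared.
#'
#' @param cm a \code{\link{connectivity_matrix}}.
#' @return list with elements \code{matrix} (normalized
#'   \code{connectivity_matrix}) and \code{total_strength}.
#' @export
normalize_strength <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  s <- sum(abs(cm$weights[upper.tri(cm$weights)]))
  if (s <= 0) stop("total connectivity strength is zero; cannot normalize")
  out <- cm
  out$weights <- cm$weights / s
  out$meta$total_strength <- s
  list(matrix = out, total_strength = s)
}

#' Mask a connectivity matrix to its positive weights
#'
#' Absolute threshold w > 0: negative and zero weights are removed and the
#' diagonal is zeroed, leaving the candidate edge set for the density sweep.
#'
#' @param cm a \code{\link{connectivity_matrix}}.
#' @return object of class \code{normalized_connectivity}: list with
#'   \code{weights} (nonnegative, symmetric, zero diagonal),
#'   \code{region_labels}, provenance and any recorded
#'   \code{total_strength}.
#' @export
mask_positive <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  diag(w) <- 0
  w[w < 0] <- 0
  if (!any(w[upper.tri(w)] > 0))
    stop("no positive off-diagonal weight survives the w > 0 threshold")
  structure(list(weights = w, region_labels = cm$region_labels,
                 subject_id = cm$subject_id, timepoint = cm$timepoint,
                 total_strength = cm$meta$total_strength),
            class = "normalized_connectivity")
}

#' Proportional density sweep with binarization
#'
#' For each density t the \code{ceiling(t * E)} strongest positive edges are
#' retained (E = number of positive off-diagonal weights) and set to 1, all
#' others to 0. Ties in weight are broken by ascending (row, column) index,
#' deterministically. Edge sets are nested along the sweep, and the result is
#' invariant to any positive rescaling of the weights.
#'
#' @param nc a \code{\link{mask_positive}} result (or a
#'   \code{connectivity_matrix}, masked on the fly).
#' @param densities density grid in (0, 1\]; default \code{seq(0.1, 1, 0.1)}.
#' @return object of class \code{density_stack}: \code{densities},
#'   \code{graphs} (list of binary adjacency matrices), \code{n_regions},
#'   \code{n_positive_edges}, provenance, and the rounding/tie policy in
#'   \code{meta}.
#' @export
density_sweep <- function(nc, densities = seq(0.1, 1, by = 0.1)) {
  if (inherits(nc, "connectivity_matrix")) nc <- mask_positive(nc)
  stopifnot(inherits(nc, "normalized_connectivity"))
  densities <- sort(unique(as.numeric(densities)))
  if (any(densities <= 0 | densities > 1))
    stop("densities must lie in (0, 1]")
  w <- nc$weights
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wts <- w[upper.tri(w)]
  pos <- wts > 0
  ut <- ut[pos, , drop = FALSE]
  wts <- wts[pos]
  n_edges <- length(wts)
  # strongest first; ties by ascending (row, col)
  ord <- order(-wts, ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  graphs <- lapply(densities, function(t) {
    m <- ceiling(t * n_edges)
    adj <- matrix(0L, n, n)
    if (m > 0) {
      sel <- ut[seq_len(m), , drop = FALSE]
      adj[sel] <- 1L
      adj[sel[, c(2L, 1L), drop = FALSE]] <- 1L
    }
    dimnames(adj) <- list(nc$region_labels, nc$region_labels)
    adj
  })
  structure(list(densities = densities, graphs = graphs,
                 n_regions = n, n_positive_edges = n_edges,
                 region_labels = nc$region_labels,
                 subject_id = nc$subject_id, timepoint = nc$timepoint,
                 meta = list(rounding = "ceiling", ties = "ascending-index",
                             total_strength = nc$total_strength)),
            class = "density_stack")
}

#' @export
print.density_stack <- function(x, ...) {
  cat(sprintf("Density graph stack: %d regions, %d positive edges (%s, %s)\n",
              x$n_regions, x$n_positive_edges, x$subject_id, x$timepoint))
  cat("  densities:", paste(format(x$densities), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a density stack to a directory of delimited matrices
#'
#' One tab-separated 0/1 matrix per density plus a JSON manifest recording
#' densities, edge counts and the rounding and tie policies.
#'
#' @param stack a \code{density_stack}.
#' @param dir output directory (created if missing).
#' @export
write_density_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "density_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("graph_density_%03d.tsv", round(stack$densities * 100))
  for (i in seq_along(stack$graphs))
    utils::write.table(stack$graphs[[i]], file.path(dir, files[i]),
                       sep = "\t", quote = FALSE, col.names = NA)
  manifest <- list(densities = stack$densities, files = files,
                   n_regions = stack$n_regions,
                   n_positive_edges = stack$n_positive_edges,
                   rounding = stack$meta$rounding, ties = stack$meta$ties)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
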