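# Simulated second lesions: serial random / degree-targeted node deletion and
# clinically representative node-set attacks, with AUC summaries of
# post-attack global efficiency.

#' Lesion node set
#'
#' @param name label (e.g. "cortical").
#' @param node_ids integer region indices the lesion covers.
#' @param source \code{"list"} (supplied ids) or \code{"atlas-overlap"}.
#' @param volume_cm3 optional lesion volume.
#' @return object of class \code{lesion_node_set}.
#' @export
lesion_node_set <- function(name, node_ids, source = "list",
                            volume_cm3 = NULL) {
  structure(list(name = name, node_ids = sort(unique(as.integer(node_ids))),
                 source = source, volume_cm3 = volume_cm3),
            class = "lesion_node_set")
}

#' @export
print.lesion_node_set <- function(x, ...) {
  cat(sprintf("Lesion '%s': %d nodes (%s)%s\n", x$name, length(x$node_ids),
              x$source,
              if (is.null(x$volume_cm3)) "" else
                sprintf(", %.1f cm^3", x$volume_cm3)))
  invisible(x)
}

#' Read a lesion node set from a one-id-per-line text file
#'
#' @param path text file with one integer region index per line.
#' @param name label for the set (default: file name).
#' @return a \code{\link{lesion_node_set}}.
#' @export
read_lesion_nodes <- function(path, name = NULL) {
  ids <- scan(path, what = integer(), quiet = TRUE)
  lesion_node_set(if (is.null(name)) basename(path) else name, ids, "list")
}

#' Delete nodes from a binary graph
#'
#' Removes the rows and columns of the given nodes; downstream efficiency is
#' computed on the induced subgraph (N = remaining node count).
#'
#' @param adj symmetric binary adjacency matrix.
#' @param nodes integer node indices to delete; must leave at least 2 nodes.
#' @return adjacency matrix on the remaining nodes.
#' @export
delete_nodes <- function(adj, nodes) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  nodes <- unique(as.integer(nodes))
  if (length(nodes) == 0L) return(adj)
  if (any(nodes < 1L | nodes > n)) stop("node index outside the graph")
  if (n - length(nodes) < 2L)
    stop("deletion would leave fewer than 2 nodes")
  adj[-nodes, -nodes, drop = FALSE]
}

# Efficiency of the subgraph induced by `remaining` (0 by convention when
# fewer than 2 nodes remain).
subgraph_efficiency <- function(adj, remaining) {
  if (length(remaining) < 2L) return(0)
  global_efficiency(adj[remaining, remaining, drop = FALSE])
}

attack_result <- function(strategy, stack, per_density_curves,
                          per_density_summary, n_deleted,
                          range_lo, range_hi, replicate_seeds = NULL,
                          extra = list()) {
  structure(c(list(strategy = strategy,
                   densities = stack$densities,
                   per_density_curves = per_density_curves,
                   per_density_summary = per_density_summary,
                   summary_auc = if (sum(stack$densities >= range_lo - 1e-9 &
                                           stack$densities <= range_hi + 1e-9) >= 2L)
                     auc_over_density(stack$densities, per_density_summary,
                                      range_lo, range_hi) else NA_real_,
                   range = c(range_lo, range_hi),
                   n_deleted = n_deleted,
                   replicate_seeds = replicate_seeds,
                   subject_id = stack$subject_id,
                   timepoint = stack$timepoint), extra),
            class = "attack_result")
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("Attack '%s' on %s/%s: %d node(s) deleted, AUC[%g, %g] = %.6g\n",
              x$strategy, x$subject_id, x$timepoint, x$n_deleted,
              x$range[1L], x$range[2L], x$summary_auc))
  invisible(x)
}

# Serial attack core: for a deletion order per density, compute the
# efficiency-after-each-step curve. Steps leaving fewer than 2 nodes
# contribute 0 by convention; the per-density summary averages steps
# 1..(N-2).
serial_curve <- function(adj, order) {
  n <- nrow(adj)
  curve <- numeric(n)
  remaining <- seq_len(n)
  for (k in seq_len(n)) {
    remaining <- remaining[remaining != order[k]]
    curve[k] <- subgraph_efficiency(adj, remaining)
  }
  curve
}

#' Serial random attack
#'
#' Deletes all nodes one at a time in a uniformly random order, recomputing
#' global efficiency on the remaining induced subgraph after every deletion
#' at every density. Curves are averaged over \code{n_replicates} random
#' orders, then over deletion steps 1..N-2 (steps leaving fewer than 2 nodes
#' count 0 by convention) to one value per density; the AUC of that
#' per-density summary over the analysis range is the subject-level
#' resilience value.
#'
#' @param stack a \code{\link{density_sweep}} result.
#' @param n_replicates number of random deletion orders (default 20).
#' @param seed integer seed for the replicate orders.
#' @param range_lo,range_hi analysis range for the AUC.
#' @return an \code{attack_result}; \code{per_density_curves} is a steps x
#'   densities matrix of replicate-averaged efficiencies.
#' @export
serial_random_attack <- function(stack, n_replicates = 20, seed = 1L,
                                 range_lo = 0.3, range_hi = 1.0) {
  stopifnot(inherits(stack, "density_stack"), n_replicates >= 1)
  n <- stack$n_regions
  nd <- length(stack$densities)
  set.seed(as.integer(seed))
  acc <- matrix(0, n, nd)
  for (r in seq_len(n_replicates)) {
    ord <- sample.int(n)
    for (d in seq_len(nd))
      acc[, d] <- acc[, d] + serial_curve(stack$graphs[[d]], ord)
  }
  curves <- acc / n_replicates
  summary <- colMeans(curves[seq_len(max(1L, n - 2L)), , drop = FALSE])
  attack_result("random", stack, curves, summary, n, range_lo, range_hi,
                replicate_seeds = seed,
                extra = list(n_replicates = n_replicates))
}

# Degree-descending deletion order, ties by ascending node id.
targeted_order <- function(adj, adaptive = FALSE) {
  n <- nrow(adj)
  if (!adaptive) {
    deg <- colSums(adj != 0)
    return(order(-deg, seq_len(n)))
  }
  remaining <- seq_len(n)
  a <- adj != 0
  ord <- integer(n)
  for (k in seq_len(n)) {
    deg <- colSums(a[remaining, remaining, drop = FALSE])
    pick <- remaining[order(-deg, remaining)[1L]]
    ord[k] <- pick
    remaining <- remaining[remaining != pick]
  }
  ord
}

#' Serial degree-targeted attack
#'
#' Deletes nodes by decreasing order of node degree (ties by ascending node
#' id), per density graph. By default the order is fixed from the intact
#' graph; with \code{recompute = TRUE} degrees are re-ranked among the
#' remaining nodes after every deletion. Step averaging and AUC summary as in
#' \code{\link{serial_random_attack}}.
#'
#' @param stack a \code{\link{density_sweep}} result.
#' @param recompute re-rank degrees adaptively after each deletion.
#' @param range_lo,range_hi analysis range for the AUC.
#' @return an \code{attack_result}.
#' @export
serial_targeted_attack <- function(stack, recompute = FALSE,
                                   range_lo = 0.3, range_hi = 1.0) {
  stopifnot(inherits(stack, "density_stack"))
  n <- stack$n_regions
  curves <- vapply(stack$graphs, function(adj)
    serial_curve(adj, targeted_order(adj, adaptive = recompute)),
    numeric(n))
  curves <- matrix(curves, nrow = n)
  summary <- colMeans(curves[seq_len(max(1L, n - 2L)), , drop = FALSE])
  attack_result("targeted", stack, curves, summary, n, range_lo, range_hi,
                extra = list(adaptive = recompute))
}

#' Clinically representative (lesion-mask) attack
#'
#' Deletes the whole lesion node set at once and reports the post-attack
#' global efficiency at each density plus its AUC over the analysis range.
#'
#' @param stack a \code{\link{density_sweep}} result.
#' @param lesion a \code{\link{lesion_node_set}} or integer node-id vector;
#'   must be nonempty and leave at least 2 nodes.
#' @param range_lo,range_hi analysis range for the AUC.
#' @return an \code{attack_result}; \code{per_density_curves} has one row
#'   (the post-deletion efficiency per density).
#' @export
mask_attack <- function(stack, lesion, range_lo = 0.3, range_hi = 1.0) {
  stopifnot(inherits(stack, "density_stack"))
  if (inherits(lesion, "lesion_node_set")) {
    name <- lesion$name
    nodes <- lesion$node_ids
  } else {
    name <- "mask"
    nodes <- sort(unique(as.integer(lesion)))
  }
  if (length(nodes) == 0L) stop("lesion node set is empty")
  n <- stack$n_regions
  if (any(nodes < 1L | nodes > n)) stop("lesion node outside the graph")
  if (n - length(nodes) < 2L) stop("lesion leaves fewer than 2 nodes")
  remaining <- setdiff(seq_len(n), nodes)
  post <- vapply(stack$graphs, subgraph_efficiency, numeric(1),
                 remaining = remaining)
  attack_result(paste0("mask:", name), stack,
                matrix(post, nrow = 1L), post, length(nodes),
                range_lo, range_hi,
                extra = list(lesion_nodes = nodes))
}

#' Map a lesion mask volume to atlas regions
#'
#' A region is included when the fraction of its voxels inside the binary
#' lesion mask is positive and at least \code{min_overlap_fraction} (default
#' 0: any overlap). Mask and atlas must share the voxel grid; when both carry
#' NIfTI orientation information the affines are compared too. The mask
#' volume in cm^3 is derived from the voxel size.
#'
#' @param mask binary lesion volume: 3D array, \code{RNifti} image, or path
#'   to a NIfTI file.
#' @param atlas integer label volume on the same grid (same types accepted).
#' @param min_overlap_fraction minimal overlapping voxel fraction of a region
#'   for inclusion.
#' @param name label for the resulting set.
#' @param voxel_dims voxel edge lengths in mm, used when plain arrays are
#'   given (default \code{c(1, 1, 1)}).
#' @return a \code{\link{lesion_node_set}} (source \code{"atlas-overlap"})
#'   with an \code{overlap} attribute giving per-region overlap fractions.
#' @export
mask_to_nodes <- function(mask, atlas, min_overlap_fraction = 0,
                          name = "mask", voxel_dims = c(1, 1, 1)) {
  load_vol <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("reading NIfTI files requires the RNifti package")
      RNifti::readNifti(x)
    } else x
  }
  mask <- load_vol(mask)
  atlas <- load_vol(atlas)
  if (!identical(dim(mask), dim(atlas)))
    stop(sprintf("voxel grids differ: mask %s vs atlas %s",
                 paste(dim(mask), collapse = "x"),
                 paste(dim(atlas), collapse = "x")))
  if (inherits(mask, "niftiImage") && inherits(atlas, "niftiImage")) {
    xm <- RNifti::xform(mask)
    xa <- RNifti::xform(atlas)
    if (max(abs(xm - xa)) > 1e-4)
      stop("mask and atlas affines differ:\nmask:\n",
           paste(utils::capture.output(print(xm)), collapse = "\n"),
           "\natlas:\n",
           paste(utils::capture.output(print(xa)), collapse = "\n"))
    voxel_dims <- RNifti::pixdim(mask)[1:3]
  }
  m <- as.array(mask) > 0
  a <- as.array(atlas)
  ids <- sort(unique(a[a > 0]))
  frac <- vapply(ids, function(r) {
    vox <- a == r
    sum(m & vox) / sum(vox)
  }, numeric(1))
  names(frac) <- ids
  keep <- frac > 0 & frac >= min_overlap_fraction
  vol <- sum(m) * prod(voxel_dims) / 1000  # mm^3 -> cm^3
  out <- lesion_node_set(name, as.integer(ids[keep]), "atlas-overlap",
                         volume_cm3 = vol)
  attr(out, "overlap") <- frac
  out
}

#' Write an attack result as CSV plus a JSON summary
#'
#' The CSV holds one row per (density, step) with the post-deletion
#' efficiency; the JSON sidecar records strategy, deletion count, analysis
#' range and the summary AUC.
#'
#' @param res an \code{attack_result}.
#' @param path CSV path; JSON goes to \code{<path>.json}.
#' @export
write_attack_result <- function(res, path) {
  stopifnot(inherits(res, "attack_result"))
  curves <- res$per_density_curves
  df <- data.frame(density = rep(res$densities, each = nrow(curves)),
                   step = rep(seq_len(nrow(curves)), length(res$densities)),
                   value = as.vector(curves))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(strategy = res$strategy,
                            n_deleted = res$n_deleted,
                            range = res$range,
                            per_density_summary = res$per_density_summary,
                            summary_auc = res$summary_auc),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
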