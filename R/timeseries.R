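#' Regional time-series container
#'
#' A T x N matrix of regional BOLD signals with sampling interval and region
#' labels; the unit every cleaning step consumes and produces.
#'
#' @param data numeric T x N matrix (rows = time points, columns = regions).
#' @param sampling_interval sampling interval in seconds.
#' @param region_labels character vector of N region labels; defaults to
#'   column names or \code{R001..}.
#' @param subject_id,timepoint provenance labels.
#' @return object of class \code{regional_ts}.
#' @export
regional_ts <- function(data, sampling_interval, region_labels = NULL,
                        subject_id = "subject", timepoint = "TP1") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(nrow(data) >= 2, ncol(data) >= 1, sampling_interval > 0)
  if (is.null(region_labels)) {
    region_labels <- colnames(data)
    if (is.null(region_labels))
      region_labels <- sprintf("R%03d", seq_len(ncol(data)))
  }
  stopifnot(length(region_labels) == ncol(data))
  colnames(data) <- region_labels
  structure(list(data = data, sampling_interval = sampling_interval,
                 region_labels = region_labels, subject_id = subject_id,
                 timepoint = timepoint, meta = list()),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("Regional time series: %d volumes x %d regions @ %.2f s (%s, %s)\n",
              nrow(x$data), ncol(x$data), x$sampling_interval,
              x$subject_id, x$timepoint))
  if (length(x$meta)) cat("  processing:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.regional_ts <- function(x) dim(x$data)

ts_replace <- function(ts, data, step = NULL, info = TRUE) {
  colnames(data) <- ts$region_labels
  ts$data <- data
  if (!is.null(step)) ts$meta[[step]] <- info
  ts
}

#' Clean regional time series
#'
#' Applies, in order: removal of the first \code{n_discard} volumes
#' (magnetization equilibrium), per-region linear detrending by least squares,
#' optional division by the pre-detrend region mean, and ordinary
#' least-squares projection of nuisance regressors (motion parameters, their
#' derivatives, mean CSF signal -- any subset) out of every region. The
#' nuisance projection includes intercept and trend in its design matrix, so
#' residuals are orthogonal to all regressors and cleaning is idempotent.
#'
#' @param ts a \code{\link{regional_ts}}.
#' @param nuisance optional T x K numeric matrix of nuisance regressors on the
#'   same time grid as the input (rows discarded together with the signal).
#' @param n_discard number of initial volumes to drop (default 5).
#' @param scale_by_region_mean divide each region by its pre-detrend mean.
#' @return cleaned \code{regional_ts} with T - n_discard volumes.
#' @export
clean_series <- function(ts, nuisance = NULL, n_discard = 5L,
                         scale_by_region_mean = FALSE) {
  stopifnot(inherits(ts, "regional_ts"))
  x <- ts$data
  if (n_discard >= nrow(x)) stop("n_discard must be smaller than T")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(x))
      stop("nuisance matrix must have the same number of rows as the series")
  }
  if (n_discard > 0L) {
    keep <- (n_discard + 1L):nrow(x)
    x <- x[keep, , drop = FALSE]
    if (!is.null(nuisance)) nuisance <- nuisance[keep, , drop = FALSE]
  }
  t_len <- nrow(x)
  if (!is.null(nuisance) && t_len <= ncol(nuisance) + 2L)
    stop("too few volumes for the number of nuisance regressors")

  mu <- colMeans(x)
  trend <- cbind(1, seq_len(t_len))
  x <- stats::lm.fit(trend, x)$residuals
  if (scale_by_region_mean) {
    tiny <- abs(mu) < 1e-10 * max(1, max(abs(mu)))
    if (any(tiny))
      stop("region mean ~ 0, cannot scale by mean: ",
           paste(ts$region_labels[tiny], collapse = ", "))
    x <- sweep(x, 2L, mu, "/")
  }
  if (!is.null(nuisance) && ncol(nuisance) > 0L) {
    # one design matrix (intercept + trend + nuisance), as in standard fMRI
    # cleaning: residuals are orthogonal to every regressor, making the
    # projection exact and idempotent
    qrn <- qr(cbind(1, seq_len(t_len), nuisance))
    if (qrn$rank < ncol(nuisance) + 2L)
      stop("nuisance regressor matrix is rank deficient")
    x <- qr.resid(qrn, x)
  }
  out <- ts_replace(ts, x, "cleaned",
                    list(n_discard = n_discard,
                         scaled = scale_by_region_mean,
                         n_nuisance = if (is.null(nuisance)) 0L else ncol(nuisance)))
  out
}

#' Winsorize regional time series
#'
#' Per region, values below the \code{lower_pct} percentile are set to that
#' percentile and values above \code{upper_pct} to that one. Percentiles use
#' linear interpolation between order statistics (\code{\link[stats]{quantile}}
#' type 7).
#'
#' @param ts a \code{\link{regional_ts}}.
#' @param lower_pct,upper_pct percentile bounds in \[0, 100\] with
#'   \code{lower_pct < upper_pct}; defaults 5 and 95.
#' @return winsorized \code{regional_ts}.
#' @export
winsorize_series <- function(ts, lower_pct = 5, upper_pct = 95) {
  stopifnot(inherits(ts, "regional_ts"),
            lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  x <- apply(ts$data, 2L, function(col) {
    q <- stats::quantile(col, c(lower_pct, upper_pct) / 100,
                         names = FALSE, type = 7)
    pmin(pmax(col, q[1L]), q[2L])
  })
  ts_replace(ts, x, "winsorized", c(lower_pct, upper_pct))
}

#' Framewise displacement from realignment parameters
#'
#' Power-style scalar head-motion summary:
#' \code{FD_t = sum(|d translation|) + head_radius * sum(|d rotation|)},
#' rotations converted to arc length on a sphere of radius
#' \code{head_radius}; the first volume has FD 0 by convention.
#'
#' @param motion T x 6 matrix: columns 1-3 translations (mm), 4-6 rotations
#'   (radians).
#' @param head_radius sphere radius in mm (default 50).
#' @return numeric vector of length T (mm).
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) >= 2, ncol(motion) == 6)
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Pearson connectivity matrix
#'
#' Pairwise sample Pearson correlations between all regions of a cleaned
#' series.
#'
#' @param ts a \code{\link{regional_ts}} with positive variance in every
#'   region.
#' @return a \code{\link{connectivity_matrix}}.
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(inherits(ts, "regional_ts"))
  v <- apply(ts$data, 2L, stats::var)
  if (any(v <= 0))
    stop("zero-variance region(s): ",
         paste(ts$region_labels[v <= 0], collapse = ", "))
  connectivity_matrix(stats::cor(ts$data),
                      region_labels = ts$region_labels,
                      subject_id = ts$subject_id, timepoint = ts$timepoint)
}

#' Connectivity-matrix container
#'
#' Symmetric N x N matrix of Pearson correlations; the central object of the
#' pipeline. The diagonal is ignored by every downstream operation.
#'
#' @param weights symmetric numeric matrix with off-diagonal entries in
#'   \[-1, 1\].
#' @param region_labels,subject_id,timepoint provenance.
#' @return object of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(weights, region_labels = NULL,
                                subject_id = "subject", timepoint = "TP1") {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(n == ncol(weights), n >= 2)
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("connectivity matrix must be symmetric")
  off <- weights[upper.tri(weights)]
  if (any(off < -1 - 1e-8 | off > 1 + 1e-8))
    stop("off-diagonal weights must lie in [-1, 1]")
  weights <- (weights + t(weights)) / 2
  if (is.null(region_labels)) {
    region_labels <- rownames(weights)
    if (is.null(region_labels)) region_labels <- sprintf("R%03d", seq_len(n))
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, region_labels = region_labels,
                 subject_id = subject_id, timepoint = timepoint,
                 meta = list()),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf("Connectivity matrix: %d regions (%s, %s); weights %.3f..%.3f\n",
              nrow(x$weights), x$subject_id, x$timepoint, min(off), max(off)))
  invisible(x)
}

#' Flip left and right hemispheres of a connectivity matrix
#'
#' Applies the simultaneous row/column permutation swapping each homotopic
#' pair, so that (for patients with right-sided lesions) all lesions can be
#' analyzed as if on the same side. Flipping is an involution: applying it
#' twice returns the original matrix bit-exactly.
#'
#' @param cm a \code{\link{connectivity_matrix}}.
#' @param pairing a \code{\link{homotopic_pairing}} covering the matrix's
#'   regions.
#' @return flipped \code{connectivity_matrix}.
#' @export
flip_hemispheres <- function(cm, pairing) {
  stopifnot(inherits(cm, "connectivity_matrix"),
            inherits(pairing, "homotopic_pairing"))
  n <- nrow(cm$weights)
  covered <- sort(c(as.integer(pairing$pairs), pairing$unpaired))
  if (!identical(covered, seq_len(n)))
    stop("pairing does not cover regions: ",
         paste(setdiff(seq_len(n), covered), collapse = ", "))
  perm <- pairing_permutation(pairing)
  out <- cm
  out$weights <- cm$weights[perm, perm]
  dimnames(out$weights) <- dimnames(cm$weights)
  out$meta$flipped <- !isTRUE(cm$meta$flipped)
  out
}

#' Write / read regional time series as delimited text
#'
#' Tab-separated, one header row of region labels, full double precision
#' (\code{\%.17g}) so matrices round-trip losslessly.
#'
#' @param ts a \code{\link{regional_ts}}.
#' @param path file path.
#' @export
write_regional_ts <- function(ts, path) {
  stopifnot(inherits(ts, "regional_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ts$region_labels, collapse = "\t"), con)
  writeLines(apply(ts$data, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_regional_ts
#' @param sampling_interval,subject_id,timepoint metadata for the object
#'   (not stored in the text file).
#' @export
read_regional_ts <- function(path, sampling_interval, subject_id = "subject",
                             timepoint = "TP1") {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  regional_ts(as.matrix(x), sampling_interval = sampling_interval,
              region_labels = colnames(x), subject_id = subject_id,
              timepoint = timepoint)
}

#' Write / read a connectivity matrix as delimited text
#'
#' Tab-separated with a leading label column and header row; full double
#' precision for lossless round trips.
#'
#' @param cm a \code{\link{connectivity_matrix}}.
#' @param path file path.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", cm$region_labels), collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(cm$weights)), function(i)
    paste(c(cm$region_labels[i], sprintf("%.17g", cm$weights[i, ])),
          collapse = "\t"), character(1)), con)
  invisible(path)
}

#' @rdname write_connectivity
#' @param subject_id,timepoint metadata for the object.
#' @export
read_connectivity <- function(path, subject_id = "subject", timepoint = "TP1") {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         row.names = 1L)
  connectivity_matrix(as.matrix(x), region_labels = colnames(x),
                      subject_id = subject_id, timepoint = timepoint)
}
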