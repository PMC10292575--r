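#' Specify a synthetic longitudinal cohort
#'
#' Defines the generating law for a synthetic resting-state cohort: regional
#' time series are stationary vector AR(1) processes whose stationary
#' correlation matrix has community-block structure (correlation
#' \code{within_community_corr} inside a community, \code{between_community_corr}
#' across communities). Patients are scanned at three timepoints (TP1-TP3),
#' controls once. At patient TP3 the between-community correlation is raised
#' by \code{tp3_effect}, which jointly increases connectivity density, mean
#' degree and global efficiency downstream.
#'
#' Communities are mirrored across hemispheres: with the default homotopic
#' layout (region \code{i} paired with \code{i + n_regions/2}) a community
#' consists of a left block and its right homologue, so hemisphere flipping
#' preserves community labels.
#'
#' @param n_patients number of patients (3 timepoints each).
#' @param n_controls number of controls (1 timepoint each); may be 0.
#' @param n_regions number of atlas regions (default 240).
#' @param n_volumes number of time points per series (default 395).
#' @param sampling_interval sampling interval in seconds (default 1.2).
#' @param n_communities number of communities; \code{n_regions/2} must be a
#'   multiple of \code{n_communities}.
#' @param within_community_corr stationary correlation inside a community,
#'   in \[0, 1).
#' @param between_community_corr stationary correlation across communities;
#'   must be strictly less than \code{within_community_corr}.
#' @param ar1_coefficient lag-1 autoregressive coefficient shared by all
#'   regions, in \[0, 1).
#' @param tp3_effect additive increase of the between-community correlation at
#'   patient TP3 (>= 0).
#' @param right_lesion_fraction probability that a patient's lesion is on the
#'   right (default 0.25, i.e. 4 of 16).
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   cohorts.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 16, n_controls = 16,
                        n_regions = 240, n_volumes = 395,
                        sampling_interval = 1.2,
                        n_communities = 6,
                        within_community_corr = 0.5,
                        between_community_corr = 0.1,
                        ar1_coefficient = 0.3,
                        tp3_effect = 0,
                        right_lesion_fraction = 0.25,
                        seed = 1L) {
  stopifnot(n_patients >= 0, n_controls >= 0, n_regions >= 4,
            n_volumes >= 8, sampling_interval > 0, n_communities >= 1,
            tp3_effect >= 0,
            right_lesion_fraction >= 0, right_lesion_fraction <= 1)
  if (n_regions %% 2L != 0L)
    stop("n_regions must be even (homotopic left/right pairing)")
  if ((n_regions / 2L) %% n_communities != 0L)
    stop("n_regions/2 must be a multiple of n_communities")
  if (within_community_corr < 0 || within_community_corr >= 1)
    stop("within_community_corr must be in [0, 1)")
  if (between_community_corr < 0 || between_community_corr >= 1)
    stop("between_community_corr must be in [0, 1)")
  if (within_community_corr <= between_community_corr)
    stop("within_community_corr must exceed between_community_corr")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stop("ar1_coefficient must be in [0, 1)")
  spec <- list(n_patients = as.integer(n_patients),
               n_controls = as.integer(n_controls),
               n_regions = as.integer(n_regions),
               n_volumes = as.integer(n_volumes),
               sampling_interval = sampling_interval,
               n_communities = as.integer(n_communities),
               within_community_corr = within_community_corr,
               between_community_corr = between_community_corr,
               ar1_coefficient = ar1_coefficient,
               tp3_effect = tp3_effect,
               right_lesion_fraction = right_lesion_fraction,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  # both generating covariances must be positive semi-definite before any
  # sampling happens
  check_psd(block_correlation(spec$n_regions, spec$n_communities,
                              within_community_corr, between_community_corr),
            "baseline")
  if (tp3_effect > 0)
    check_psd(block_correlation(spec$n_regions, spec$n_communities,
                                within_community_corr,
                                between_community_corr + tp3_effect),
              "TP3")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d patients (TP1-TP3), %d controls (single TP)\n",
              x$n_patients, x$n_controls))
  cat(sprintf("  %d regions, %d volumes @ %.2f s, %d communities\n",
              x$n_regions, x$n_volumes, x$sampling_interval, x$n_communities))
  cat(sprintf("  corr within %.3f / between %.3f, AR(1) %.2f, TP3 effect +%.3f\n",
              x$within_community_corr, x$between_community_corr,
              x$ar1_coefficient, x$tp3_effect))
  invisible(x)
}

#' Mirrored community labels
#'
#' Assigns each region a community such that homotopic partners
#' (\code{i}, \code{i + n_regions/2}) share a label: each community is a
#' contiguous block within each hemisphere.
#'
#' @param n_regions even region count.
#' @param n_communities number of communities dividing \code{n_regions/2}.
#' @return integer vector of length \code{n_regions} with values in
#'   \code{1:n_communities}.
#' @export
community_labels <- function(n_regions, n_communities) {
  half <- n_regions %/% 2L
  stopifnot(n_regions %% 2L == 0L, half %% n_communities == 0L)
  rep(rep(seq_len(n_communities), each = half %/% n_communities), 2L)
}

block_correlation <- function(n_regions, n_communities, r_within, r_between) {
  comm <- community_labels(n_regions, n_communities)
  same <- outer(comm, comm, "==")
  sigma <- matrix(r_between, n_regions, n_regions)
  sigma[same] <- r_within
  diag(sigma) <- 1
  sigma
}

check_psd <- function(sigma, label) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop(sprintf(paste0("implied %s covariance is not positive semi-definite ",
                        "(min eigenvalue %.3g); lower the community ",
                        "correlations or the TP3 effect"),
                 label, min(ev)))
  invisible(TRUE)
}

#' Default homotopic pairing
#'
#' By convention region \code{i} in the left hemisphere is paired with region
#' \code{i + n_regions/2} on the right; an odd trailing region count can be
#' declared midline via \code{unpaired}.
#'
#' @param n_regions total region count.
#' @param pairs optional two-column matrix of (left, right) indices; default
#'   \code{(i, i + n_regions/2)}.
#' @param unpaired indices of midline regions belonging to no pair.
#' @return object of class \code{homotopic_pairing}.
#' @export
homotopic_pairing <- function(n_regions, pairs = NULL, unpaired = integer(0)) {
  if (is.null(pairs)) {
    if (n_regions %% 2L != 0L)
      stop("default pairing needs an even n_regions; supply pairs explicitly")
    half <- n_regions %/% 2L
    pairs <- cbind(seq_len(half), seq_len(half) + half)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  idx <- c(pairs, as.integer(unpaired))
  if (anyDuplicated(idx))
    stop("a region appears more than once across pairs and unpaired")
  if (length(idx) && (min(idx) < 1L || max(idx) > n_regions))
    stop("pairing indices outside 1..n_regions")
  structure(list(pairs = pairs, unpaired = as.integer(unpaired),
                 n_regions = as.integer(n_regions)),
            class = "homotopic_pairing")
}

pairing_permutation <- function(pairing) {
  perm <- seq_len(pairing$n_regions)
  perm[pairing$pairs[, 1L]] <- pairing$pairs[, 2L]
  perm[pairing$pairs[, 2L]] <- pairing$pairs[, 1L]
  perm
}

# Draw a stationary vector AR(1) series of length t_len whose stationary
# covariance is sigma: x_1 ~ N(0, sigma), x_t = phi x_{t-1} + e_t with
# e_t ~ N(0, (1 - phi^2) sigma).
ar1_series <- function(t_len, chol_sigma, phi) {
  n <- ncol(chol_sigma)
  z <- matrix(stats::rnorm(t_len * n), t_len, n) %*% chol_sigma
  if (phi == 0) return(z)
  x <- matrix(0, t_len, n)
  x[1L, ] <- z[1L, ]
  s <- sqrt(1 - phi^2)
  for (t in 2:t_len) x[t, ] <- phi * x[t - 1L, ] + s * z[t, ]
  x
}

chol_psd <- function(sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    # boundary-PSD matrices: eigendecomposition square root
    eg <- eigen(sigma, symmetric = TRUE)
    ch <- diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  }
  ch
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws one regional time series per subject and timepoint (patients: TP1,
#' TP2, TP3; controls: a single session) from the law described by the
#' \code{cohort_spec}, together with the long-format cohort table used by the
#' statistics stage. Patient TP3 series are drawn with the between-community
#' correlation raised by \code{tp3_effect}; all other sessions share the
#' baseline law, so with \code{tp3_effect = 0} every session is an exchangeable
#' draw. Each patient receives a lesion side (right with probability
#' \code{right_lesion_fraction}) and a log-normal lesion volume in cm^3,
#' independent of the planted effect.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param pairing optional \code{\link{homotopic_pairing}}; defaults to the
#'   (i, i + N/2) convention and is stored on the output for downstream
#'   flipping.
#' @return a list with elements \code{series} (named list of
#'   \code{\link{regional_ts}}, names \code{"<subject>_<timepoint>"}),
#'   \code{cohort} (data.frame: subject_id, group, timepoint, lesion_side,
#'   lesion_volume_cm3), \code{communities}, \code{pairing} and \code{spec}.
#' @export
generate_cohort <- function(spec, pairing = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(pairing)) pairing <- homotopic_pairing(spec$n_regions)
  set.seed(spec$seed)
  comm <- community_labels(spec$n_regions, spec$n_communities)
  labels <- sprintf("R%03d", seq_len(spec$n_regions))
  sigma0 <- block_correlation(spec$n_regions, spec$n_communities,
                              spec$within_community_corr,
                              spec$between_community_corr)
  ch0 <- chol_psd(sigma0)
  ch3 <- if (spec$tp3_effect > 0) {
    chol_psd(block_correlation(spec$n_regions, spec$n_communities,
                               spec$within_community_corr,
                               spec$between_community_corr + spec$tp3_effect))
  } else ch0

  series <- list()
  rows <- list()
  if (spec$n_patients > 0) {
    sides <- ifelse(stats::runif(spec$n_patients) < spec$right_lesion_fraction,
                    "right", "left")
    volumes <- stats::rlnorm(spec$n_patients, meanlog = log(8), sdlog = 0.6)
    for (p in seq_len(spec$n_patients)) {
      sid <- sprintf("P%02d", p)
      for (tp in c("TP1", "TP2", "TP3")) {
        ch <- if (tp == "TP3") ch3 else ch0
        x <- ar1_series(spec$n_volumes, ch, spec$ar1_coefficient)
        series[[paste(sid, tp, sep = "_")]] <-
          regional_ts(x, sampling_interval = spec$sampling_interval,
                      region_labels = labels, subject_id = sid, timepoint = tp)
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = sid, group = "patient", timepoint = tp,
                     lesion_side = sides[p], lesion_volume_cm3 = volumes[p],
                     stringsAsFactors = FALSE)
      }
    }
  }
  for (cidx in seq_len(spec$n_controls)) {
    sid <- sprintf("C%02d", cidx)
    x <- ar1_series(spec$n_volumes, ch0, spec$ar1_coefficient)
    series[[paste(sid, "single", sep = "_")]] <-
      regional_ts(x, sampling_interval = spec$sampling_interval,
                  region_labels = labels, subject_id = sid,
                  timepoint = "single")
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = sid, group = "control", timepoint = "single",
                 lesion_side = "none", lesion_volume_cm3 = NA_real_,
                 stringsAsFactors = FALSE)
  }
  list(series = series,
       cohort = do.call(rbind, rows),
       communities = comm,
       pairing = pairing,
       spec = spec)
}

#' Describe a synthetic lesion node set
#'
#' @param name label, e.g. "cortical", "subcortical", "cortico-subcortical".
#' @param node_count number of regions the lesion covers.
#' @param contiguity_rule \code{"one_community"} (nodes drawn from a single
#'   community) or \code{"adjacent_communities"} (nodes drawn from two
#'   neighbouring communities, emulating a larger middle-cerebral-artery
#'   territory lesion).
#' @return object of class \code{lesion_spec}.
#' @export
lesion_spec <- function(name, node_count,
                        contiguity_rule = c("one_community",
                                            "adjacent_communities")) {
  contiguity_rule <- match.arg(contiguity_rule)
  stopifnot(node_count >= 0)
  structure(list(name = name, node_count = as.integer(node_count),
                 contiguity_rule = contiguity_rule),
            class = "lesion_spec")
}

#' Default clinically representative lesion sizes
#'
#' Three middle-cerebral-artery stroke patterns: cortical and subcortical
#' lesions of 13 nodes each and a cortico-subcortical lesion of 54 nodes on a
#' 240-region atlas; on smaller synthetic atlases the counts are scaled
#' proportionally (rounded, minimum 1).
#'
#' @param n_regions region count of the target graphs.
#' @return list of three \code{\link{lesion_spec}} objects.
#' @export
default_lesion_specs <- function(n_regions = 240) {
  sc <- function(k) max(1L, as.integer(round(k * n_regions / 240)))
  list(lesion_spec("cortical", sc(13), "one_community"),
       lesion_spec("subcortical", sc(13), "one_community"),
       lesion_spec("cortico-subcortical", sc(54), "adjacent_communities"))
}

#' Draw lesion node sets for simulated clinically representative attacks
#'
#' @param specs list of \code{\link{lesion_spec}}.
#' @param n_regions region count.
#' @param seed integer seed (reproducible draws).
#' @param communities optional community labels; defaults to the mirrored
#'   layout of \code{\link{community_labels}} with 6 communities.
#' @return named list of sorted integer node-id vectors.
#' @export
generate_lesion_node_sets <- function(specs, n_regions, seed = 1L,
                                      communities = NULL) {
  if (inherits(specs, "lesion_spec")) specs <- list(specs)
  if (is.null(communities)) communities <- community_labels(n_regions, 6L)
  stopifnot(length(communities) == n_regions)
  set.seed(as.integer(seed))
  out <- list()
  n_comm <- max(communities)
  for (sp in specs) {
    stopifnot(inherits(sp, "lesion_spec"))
    if (sp$node_count >= n_regions)
      stop(sprintf("lesion '%s': node_count %d must be < n_regions %d",
                   sp$name, sp$node_count, n_regions))
    if (sp$node_count == 0L) {
      out[[sp$name]] <- integer(0)
      next
    }
    pool <- if (sp$contiguity_rule == "one_community") {
      sizes <- tabulate(communities, n_comm)
      ok <- which(sizes >= sp$node_count)
      if (!length(ok))
        stop(sprintf("lesion '%s': no community holds %d nodes",
                     sp$name, sp$node_count))
      which(communities == ok[sample.int(length(ok), 1L)])
    } else {
      c1 <- sample.int(n_comm - 1L, 1L)
      which(communities %in% c(c1, c1 + 1L))
    }
    if (length(pool) < sp$node_count)
      stop(sprintf("lesion '%s': pool of %d nodes < requested %d",
                   sp$name, length(pool), sp$node_count))
    out[[sp$name]] <- sort(pool[sample.int(length(pool), sp$node_count)])
  }
  out
}
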