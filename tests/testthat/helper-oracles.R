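# Independent oracles and fixture generators shared across tests.

# Per-source frontier breadth-first search; deliberately independent of the
# package's distance code (which uses boolean matrix powers / igraph).
bfs_distances_oracle <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[!is.finite(dist[nxt])]
      dist[nxt] <- lvl
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- bfs_distances_oracle(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Erdos-Renyi binary adjacency
random_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# symmetric random correlation-like matrix with weights in (-1, 1)
random_weight_matrix <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, -1, 1)
  w <- w + t(w)
  diag(w) <- 1
  w
}

# brute-force Benjamini-Hochberg step-up evaluation
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    adj[ord[i]] <- min(1, min(cands))
  }
  adj
}

# reduced synthetic study conditions used by the calibration and recovery
# suites: 8 patients, 60 regions, 120 volumes, 6 mirrored communities
reduced_spec <- function(seed, tp3_effect = 0, n_controls = 8) {
  cohort_spec(n_patients = 8, n_controls = n_controls, n_regions = 60,
              n_volumes = 120, n_communities = 6,
              within_community_corr = 0.5, between_community_corr = 0.1,
              ar1_coefficient = 0.3, tp3_effect = tp3_effect, seed = seed)
}

# pre-attack AUC(E_glob) per patient session of a generated cohort, via the
# package's standard processing chain
patient_eglob_aucs <- function(gen) {
  keys <- names(gen$series)
  pat <- grepl("^P", keys)
  vapply(keys[pat], function(k) {
    ts <- winsorize_series(clean_series(gen$series[[k]], n_discard = 0L))
    stack <- density_sweep(mask_positive(pearson_connectivity(ts)))
    attr(density_profile(stack, "global_efficiency"), "auc")
  }, numeric(1))
}
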