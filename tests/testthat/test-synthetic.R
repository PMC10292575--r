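test_that("cohort generation is deterministic under the seed", {
  spec <- cohort_spec(n_patients = 2, n_controls = 1, n_regions = 12,
                      n_volumes = 40, n_communities = 3, seed = 42)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(g1$series, g2$series)
  expect_identical(g1$cohort, g2$cohort)
})

test_that("planted block correlations are recovered empirically", {
  # Monte-Carlo check against the generating covariance: with no
  # autocorrelation, the empirical correlation of two same-community regions
  # over 10,000 samples must sit within +/-0.03 of the target 0.6
  spec <- cohort_spec(n_patients = 1, n_controls = 0, n_regions = 12,
                      n_volumes = 10000, n_communities = 2,
                      within_community_corr = 0.6,
                      between_community_corr = 0.1,
                      ar1_coefficient = 0, seed = 7)
  x <- generate_cohort(spec)$series[["P01_TP1"]]$data
  comm <- community_labels(12, 2)
  same <- which(comm == comm[1])
  expect_lt(abs(cor(x[, same[1]], x[, same[2]]) - 0.6), 0.03)
  diff_comm <- which(comm != comm[1])[1]
  expect_lt(abs(cor(x[, 1], x[, diff_comm]) - 0.1), 0.03)
})

test_that("AR(1) colouring preserves the stationary correlation", {
  spec <- cohort_spec(n_patients = 1, n_controls = 0, n_regions = 8,
                      n_volumes = 20000, n_communities = 2,
                      within_community_corr = 0.5,
                      between_community_corr = 0.1,
                      ar1_coefficient = 0.6, seed = 11)
  x <- generate_cohort(spec)$series[["P01_TP1"]]$data
  comm <- community_labels(8, 2)
  same <- which(comm == comm[1])
  expect_lt(abs(cor(x[, same[1]], x[, same[2]]) - 0.5), 0.05)
  # lag-1 autocorrelation close to the AR coefficient
  r1 <- cor(x[-1, 1], x[-nrow(x), 1])
  expect_lt(abs(r1 - 0.6), 0.05)
})

test_that("a null TP3 effect leaves timepoints exchangeable in mean weight", {
  spec <- cohort_spec(n_patients = 3, n_controls = 0, n_regions = 24,
                      n_volumes = 400, n_communities = 3, tp3_effect = 0,
                      seed = 5)
  gen <- generate_cohort(spec)
  mean_off <- function(k) {
    w <- pearson_connectivity(gen$series[[k]])$weights
    mean(w[upper.tri(w)])
  }
  m2 <- mean(vapply(paste0("P0", 1:3, "_TP2"), mean_off, numeric(1)))
  m3 <- mean(vapply(paste0("P0", 1:3, "_TP3"), mean_off, numeric(1)))
  expect_lt(abs(m3 - m2), 0.05)
})

test_that("the TP3 effect raises between-community correlation only at TP3", {
  spec <- cohort_spec(n_patients = 3, n_controls = 0, n_regions = 24,
                      n_volumes = 2000, n_communities = 3, tp3_effect = 0.2,
                      seed = 5)
  gen <- generate_cohort(spec)
  comm <- gen$communities
  between <- outer(comm, comm, "!=") & upper.tri(diag(24))
  mean_between <- function(k)
    mean(pearson_connectivity(gen$series[[k]])$weights[between])
  b2 <- mean(vapply(paste0("P0", 1:3, "_TP2"), mean_between, numeric(1)))
  b3 <- mean(vapply(paste0("P0", 1:3, "_TP3"), mean_between, numeric(1)))
  expect_gt(b3 - b2, 0.1)
})

test_that("invalid generating parameters are rejected up front", {
  expect_error(cohort_spec(within_community_corr = 0.2,
                           between_community_corr = 0.4),
               "exceed")
  # a TP3 effect pushing between-community correlation past 1 breaks
  # positive semi-definiteness and must fail naming the offending matrix
  expect_error(cohort_spec(within_community_corr = 0.5,
                           between_community_corr = 0.4, tp3_effect = 0.7),
               "positive semi-definite")
  expect_error(cohort_spec(n_regions = 241), "even")
})

test_that("homotopic pairing is a checked involution", {
  p <- homotopic_pairing(10)
  perm <- p$pairs[, 2][order(p$pairs[, 1])]
  full <- c(perm, p$pairs[, 1][order(p$pairs[, 2])])
  expect_identical(sort(full), 1:10)
  expect_error(homotopic_pairing(10, pairs = cbind(c(1, 1), c(6, 7))),
               "more than once")
  expect_error(homotopic_pairing(10, pairs = cbind(1, 11)), "outside")
})

test_that("lesion node sets honour sizes, contiguity and seeds", {
  specs <- default_lesion_specs(240)
  sets <- generate_lesion_node_sets(specs, 240, seed = 9)
  expect_identical(lengths(sets)[c("cortical", "subcortical",
                                   "cortico-subcortical")],
                   c(cortical = 13L, subcortical = 13L,
                     `cortico-subcortical` = 54L))
  comm <- community_labels(240, 6)
  expect_length(unique(comm[sets$cortical]), 1L)
  expect_lte(length(unique(comm[sets$`cortico-subcortical`])), 2L)
  expect_identical(sets, generate_lesion_node_sets(specs, 240, seed = 9))
  expect_identical(generate_lesion_node_sets(list(lesion_spec("x", 0)), 240,
                                             seed = 1)$x, integer(0))
  expect_error(generate_lesion_node_sets(list(lesion_spec("big", 240)), 240,
                                         seed = 1), "n_regions")
})
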