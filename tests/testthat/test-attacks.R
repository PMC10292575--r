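stack_from_weights <- function(w, densities = seq(0.1, 1, 0.1))
  density_sweep(connectivity_matrix(w), densities = densities)

test_that("node deletion yields the induced subgraph", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_identical(delete_nodes(k5, integer(0)), k5)
  expect_equal(global_efficiency(delete_nodes(k5, c(2, 4))), 1)
  # P4 minus an interior node: an edge plus an isolated node, E_glob = 1/3
  p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  expect_equal(global_efficiency(delete_nodes(p4, 2)), 1 / 3)
  expect_error(delete_nodes(k5, 1:4), "fewer than 2")
  expect_error(delete_nodes(k5, 7), "outside")
})

test_that("mask attack equals an independently built induced subgraph", {
  set.seed(2)
  w <- random_weight_matrix(20)
  stack <- stack_from_weights(w)
  lesion <- lesion_node_set("test", c(3, 7, 11, 15))
  res <- mask_attack(stack, lesion)
  for (i in seq_along(stack$densities)) {
    sub <- stack$graphs[[i]][-lesion$node_ids, -lesion$node_ids]
    expect_equal(res$per_density_summary[i], oracle_efficiency(sub),
                 tolerance = 1e-12)
  }
  expect_equal(res$summary_auc,
               auc_over_density(stack$densities, res$per_density_summary))
})

test_that("attack curves need not be monotone: isolated-node counterexample", {
  # K3 plus an isolated node: deleting the isolate RAISES efficiency
  adj <- matrix(0, 4, 4); adj[1:3, 1:3] <- 1; diag(adj) <- 0
  before <- global_efficiency(adj)
  after <- global_efficiency(delete_nodes(adj, 4))
  expect_equal(before, 0.5)
  expect_equal(after, 1)
  expect_gt(after, before)
})

test_that("targeted attack removes the hub first and respects the tie rule", {
  # star: deleting the hub isolates every leaf
  star <- matrix(0, 8, 8); star[1, 2:8] <- 1; star <- star + t(star)
  w <- star * 0.9; diag(w) <- 1
  stack <- density_sweep(connectivity_matrix(w), densities = 1)
  res <- serial_targeted_attack(stack)
  expect_equal(res$per_density_curves[1, 1], 0)
  # regular graph: all degrees tie, so the order is ascending node id
  ring <- matrix(0, 6, 6); ring[cbind(1:6, c(2:6, 1))] <- 1
  ring <- ring + t(ring)
  wr <- ring * 0.5; diag(wr) <- 1
  st <- density_sweep(connectivity_matrix(wr), densities = 1)
  res_t <- serial_targeted_attack(st)
  manual <- numeric(6)
  remaining <- 1:6
  for (k in 1:6) {
    remaining <- setdiff(remaining, k)
    manual[k] <- if (length(remaining) >= 2)
      oracle_efficiency(ring[remaining, remaining]) else 0
  }
  expect_equal(res_t$per_density_curves[, 1], manual)
})

test_that("targeted attacks hurt hub-dominated graphs more than random ones", {
  set.seed(9)
  g <- igraph::sample_pa(50, m = 2, directed = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  w <- adj * 0.8; diag(w) <- 1
  stack <- density_sweep(connectivity_matrix(w), densities = 1)
  tgt <- serial_targeted_attack(stack)
  rnd <- serial_random_attack(stack, n_replicates = 30, seed = 4)
  early <- 1:10
  expect_true(all(tgt$per_density_curves[early, 1] <=
                    rnd$per_density_curves[early, 1] + 1e-12))
})

test_that("random attacks are seed-deterministic and relabel-invariant", {
  set.seed(13)
  w <- random_weight_matrix(12)
  stack <- stack_from_weights(w, densities = c(0.5, 1))
  r1 <- serial_random_attack(stack, n_replicates = 5, seed = 99)
  r2 <- serial_random_attack(stack, n_replicates = 5, seed = 99)
  expect_identical(r1$per_density_curves, r2$per_density_curves)
  # node relabeling leaves the Monte-Carlo summary unchanged within error
  perm <- sample(12)
  stackp <- stack_from_weights(w[perm, perm], densities = c(0.5, 1))
  rp <- serial_random_attack(stackp, n_replicates = 400, seed = 1)
  r400 <- serial_random_attack(stack, n_replicates = 400, seed = 2)
  expect_lt(max(abs(rp$per_density_summary - r400$per_density_summary)), 0.02)
})

test_that("complete graphs keep efficiency 1 at every informative step", {
  w <- matrix(0.7, 10, 10); diag(w) <- 1
  stack <- density_sweep(connectivity_matrix(w), densities = 1)
  res <- serial_random_attack(stack, n_replicates = 3, seed = 5)
  expect_equal(res$per_density_curves[1:8, 1], rep(1, 8))
  expect_equal(res$per_density_curves[9:10, 1], c(0, 0))
  expect_equal(res$per_density_summary, 1)
})

test_that("superset lesions do at least as much damage here", {
  set.seed(21)
  w <- random_weight_matrix(30)
  stack <- stack_from_weights(w)
  small <- sort(sample(30, 5))
  big <- sort(union(small, sample(setdiff(1:30, small), 10)))
  auc_small <- mask_attack(stack, small)$summary_auc
  auc_big <- mask_attack(stack, big)$summary_auc
  expect_lte(auc_big, auc_small + 1e-12)
})

test_that("lesion masks map to atlas regions by voxel overlap", {
  atlas <- array(0L, c(10, 10, 10))
  atlas[1:2, 1:2, 1:2] <- 1L           # region 1: 8 voxels
  atlas[5:6, 5:6, 5:6] <- 2L           # region 2: 8 voxels
  mask <- array(0L, c(10, 10, 10))
  mask[1:2, 1:2, 1:2] <- 1L            # covers region 1 fully
  res <- mask_to_nodes(mask, atlas)
  expect_identical(res$node_ids, 1L)
  expect_equal(unname(attr(res, "overlap")["1"]), 1)
  # partial overlap: 2 of 8 voxels -> fraction 0.25
  mask2 <- array(0L, c(10, 10, 10))
  mask2[5:6, 5, 5] <- 1L
  res2 <- mask_to_nodes(mask2, atlas)
  expect_identical(res2$node_ids, 2L)
  expect_equal(unname(attr(res2, "overlap")["2"]), 0.25)
  expect_identical(mask_to_nodes(mask2, atlas,
                                 min_overlap_fraction = 0.3)$node_ids,
                   integer(0))
  # empty mask, volume from voxel size, grid mismatch
  empty <- mask_to_nodes(array(0L, c(10, 10, 10)), atlas,
                         voxel_dims = c(2, 2, 2))
  expect_identical(empty$node_ids, integer(0))
  expect_equal(mask_to_nodes(mask, atlas, voxel_dims = c(2, 2, 2))$volume_cm3,
               8 * 8 / 1000)
  expect_error(mask_to_nodes(array(0L, c(5, 5, 5)), atlas), "grids differ")
})

test_that("NIfTI masks round-trip through files", {
  skip_if_not_installed("RNifti")
  atlas <- array(0L, c(8, 8, 8)); atlas[1:3, 1:3, 1:3] <- 1L
  mask <- array(0L, c(8, 8, 8)); mask[2:3, 2:3, 2:3] <- 1L
  fa <- withr::local_tempfile(fileext = ".nii.gz")
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas), fa)
  RNifti::writeNifti(RNifti::asNifti(mask), fm)
  res <- mask_to_nodes(fm, fa)
  expect_identical(res$node_ids, 1L)
  expect_equal(unname(attr(res, "overlap")["1"]), 8 / 27)
})

test_that("attack results and lesion files round-trip", {
  w <- random_weight_matrix(10)
  stack <- stack_from_weights(w, densities = c(0.5, 1))
  res <- mask_attack(stack, lesion_node_set("x", c(1, 5)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_attack_result(res, f)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$summary_auc, res$summary_auc)
  lf <- withr::local_tempfile()
  writeLines(c("3", "9", "5"), lf)
  expect_identical(read_lesion_nodes(lf, "L")$node_ids, c(3L, 5L, 9L))
})
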