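patient_table <- function(values, subjects = NULL, tps = c("TP1", "TP2", "TP3"),
                          side = NULL, volume = NULL) {
  n <- length(values) / length(tps)
  if (is.null(subjects)) subjects <- sprintf("P%02d", seq_len(n))
  tb <- expand.grid(subject_id = subjects, timepoint = tps,
                    stringsAsFactors = FALSE)
  tb$group <- "patient"
  tb$outcome <- values
  tb$lesion_side <- if (is.null(side)) rep(c("left", "right"),
                                           length.out = nrow(tb)) else side
  tb$lesion_volume_cm3 <- if (is.null(volume))
    rep(seq(2, 20, length.out = n), length(tps)) else volume
  tb
}

test_that("a constant outcome gives a degenerate omnibus with p = 1", {
  tb <- patient_table(rep(3.2, 12), subjects = sprintf("P%02d", 1:4))
  res <- fit_longitudinal_model(tb)
  expect_equal(res$p_raw, 1)
  expect_match(res$method, "degenerate")
})

test_that("mixed-model omnibus matches the paired t on balanced 2-TP data", {
  set.seed(31)
  n <- 12
  base <- rnorm(n)
  tb <- patient_table(c(base + rnorm(n, sd = 0.5),
                        base + 0.4 + rnorm(n, sd = 0.5)),
                      subjects = sprintf("P%02d", 1:n), tps = c("TP1", "TP2"),
                      side = "left", volume = 1)
  res <- fit_longitudinal_model(tb)
  x1 <- tb$outcome[tb$timepoint == "TP1"]
  x2 <- tb$outcome[tb$timepoint == "TP2"]
  tt <- t.test(x2 - x1)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-6)
  expect_equal(res$method, "lmm-satterthwaite")
})

test_that("a planted 3-SD TP3 shift is detected with high power", {
  set.seed(17)
  hits <- 0
  n_sim <- 100
  for (s in seq_len(n_sim)) {
    n <- 16
    subj <- rnorm(n, sd = 1.5)
    eps <- matrix(rnorm(3 * n), n, 3)
    vals <- c(subj + eps[, 1], subj + eps[, 2], subj + 3 + eps[, 3])
    tb <- patient_table(vals, subjects = sprintf("P%02d", 1:n))
    res <- fit_longitudinal_model(tb)
    if (res$p_raw < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("pairwise comparisons handle paired, Welch and degenerate cases", {
  # identical paired vectors: zero statistic, p = 1, flagged
  tb <- patient_table(rep(c(1, 2, 3, 4), 3), subjects = sprintf("P%02d", 1:4))
  res <- pairwise_comparisons(tb, list(list(a = "TP1", b = "TP2",
                                            paired = TRUE)))
  expect_equal(res$p_raw, 1)
  expect_match(res$note, "zero variance")

  # constant nonzero paired difference: degenerate, flagged, p NA
  tb2 <- patient_table(c(1, 2, 3, 4, 2, 3, 4, 5, 2, 3, 4, 5),
                       subjects = sprintf("P%02d", 1:4))
  res2 <- pairwise_comparisons(tb2, list(list(a = "TP1", b = "TP2",
                                              paired = TRUE)))
  expect_true(is.na(res2$p_raw))
  expect_match(res2$note, "zero variance")

  # Welch t against the textbook formula
  x <- c(5.1, 4.9, 6.2, 5.8, 5.5)
  y <- c(4.2, 4.8, 4.4, 4.9, 4.6, 4.1)
  tb3 <- rbind(patient_table(rep(x, 3), subjects = sprintf("P%02d", 1:5)),
               data.frame(subject_id = sprintf("C%02d", 1:6),
                          timepoint = "single", group = "control",
                          outcome = y, lesion_side = "none",
                          lesion_volume_cm3 = NA))
  res3 <- pairwise_comparisons(tb3, list(list(a = "TP1", b = "control",
                                              paired = FALSE)))
  se <- sqrt(var(x) / 5 + var(y) / 6)
  tstat <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 5)^2 / 4 + (var(y) / 6)^2 / 5)
  p <- 2 * pt(-abs(tstat), df)
  expect_equal(res3$statistic, tstat, tolerance = 1e-10)
  expect_equal(res3$p_raw, p, tolerance = 1e-10)
})

test_that("BH adjustment implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(23)
  for (rep in 1:50) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-14))
    expect_true(all(diff(adj[order(p)]) >= -1e-14))
  }
})

test_that("the Spearman correlation matches rank arithmetic", {
  expect_equal(cost_resilience_correlation(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(cost_resilience_correlation(1:5, 5:1)$rho, -1)
  # rank formula: d = (-1, 1, -1, 1, 0), rho = 1 - 6*4/(5*24) = 0.8
  toy <- cost_resilience_correlation(1:5, c(2, 1, 4, 3, 5))
  expect_equal(toy$rho, 0.8)
  expect_equal(toy$method, "spearman-exact")
  big <- cost_resilience_correlation(1:12, rnorm(12))
  expect_equal(big$method, "spearman-t")
  expect_warning(out <- cost_resilience_correlation(rep(1, 5), 1:5),
                 "constant")
  expect_true(is.na(out$rho))
})

test_that("results tables are written with a readable report", {
  tb <- patient_table(rnorm(12), subjects = sprintf("P%02d", 1:4))
  res <- pairwise_comparisons(tb)
  f <- withr::local_tempfile(fileext = ".csv")
  write_test_results(res, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(res))
  expect_true(file.exists(paste0(f, ".txt")))
})
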