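test_that("marker rates match a brute-force confusion matrix", {
  set.seed(71)
  L <- 500
  cuts <- sort(sample(10:490, 9))
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, L)
  part <- tagcna:::new_block_partition(starts, ends,
                                       starts + (ends - starts) %/% 2L)
  p <- runif(10)
  truth <- rep(FALSE, L)
  truth[120:260] <- TRUE
  got <- marker_rates(list(p_values = p), part, truth, threshold = 0.3)

  called <- rep(FALSE, L)
  for (b in which(p < 0.3)) called[starts[b]:ends[b]] <- TRUE
  tp <- sum(called & truth); fp <- sum(called & !truth)
  expect_equal(unname(got["tpr"]), tp / sum(truth))
  expect_equal(unname(got["fpr"]), fp / sum(!truth))

  expect_equal(unname(marker_rates(list(p_values = p), part, truth, 0)),
               c(0, 0))
  # a perfect caller on truth-aligned blocks
  p2 <- ifelse(starts >= 120 & ends <= 260, 0.001, 0.9)
  truth2 <- rep(FALSE, L)
  for (b in which(p2 < 0.05)) truth2[starts[b]:ends[b]] <- TRUE
  expect_equal(unname(marker_rates(list(p_values = p2), part, truth2, 0.05)),
               c(1, 0))
})

test_that("evaluation statistics depend only on calls and truth", {
  set.seed(72)
  part <- tagcna:::new_block_partition(c(1L, 51L), c(50L, 100L), c(25L, 75L))
  truth <- c(rep(TRUE, 50), rep(FALSE, 50))
  r1 <- marker_rates(list(p_values = c(0.01, 0.5)), part, truth, 0.05)
  r2 <- marker_rates(list(p_values = c(0.01, 0.5)), part, truth, 0.05)
  expect_identical(r1, r2)
})

test_that("roc endpoints are pinned at (0,0) and (1,1)", {
  cfg <- sim_config(n_subjects = 20, n_markers = 500,
                    sce_specs = list(sce_spec(1, 60, 0.3)),
                    noise_sd_range = c(0.05, 0.1),
                    n_passengers = 1, passenger_length_range = c(10, 40),
                    seed = 73)
  sim <- simulate_cohort(cfg)
  fit <- tagcna:::fit_simulated(sim, tagcna:::run_defaults(list(E = 60)),
                                0.05, 74)
  roc <- roc_points(fit, sim$truth, thresholds = c(0, 0.05, 1.01))
  expect_equal(unname(unlist(roc[1, c("tpr", "fpr")])), c(0, 0))
  expect_equal(unname(unlist(roc[3, c("tpr", "fpr")])), c(1, 1))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
})

test_that("type-I error is zero under a degenerate cutoff", {
  cfg <- sim_config(n_subjects = 8, n_markers = 120, sce_specs = list(),
                    passenger_length_range = c(5, 15), seed = 75)
  out <- type_I_error(2, cfg, run_params = list(E = 30, w = 10), alpha = 0,
                      seed = 76)
  expect_identical(out$rate, 0)
  expect_identical(out$n_reps, 2)
})

test_that("event detection requires a polarity-matched significant overlap", {
  part <- tagcna:::new_block_partition(c(1L, 41L), c(40L, 100L), c(20L, 70L))
  mk_fit <- function(p_amp, p_del) {
    list(runs = list(
      list(chrom = "chr1", polarity = "amp", partition = part,
           peel = list(p_values = p_amp), col_offset = 0L),
      list(chrom = "chr1", polarity = "del", partition = part,
           peel = list(p_values = p_del), col_offset = 0L)),
      markers = mk_map(100))
  }
  truth <- list(sce_intervals = data.frame(
    start = c(10L, 60L), end = c(30L, 90L), polarity = c("amp", "del")))

  both <- mk_fit(c(0.01, 0.9), c(0.9, 0.01))
  expect_true(tagcna:::all_truth_detected(both, truth, 0.05))
  # significant block on the wrong polarity does not count
  wrong <- mk_fit(c(0.01, 0.01), c(0.9, 0.9))
  expect_false(tagcna:::all_truth_detected(wrong, truth, 0.05))
  # a single missed event fails the pair
  half <- mk_fit(c(0.01, 0.9), c(0.9, 0.9))
  expect_false(tagcna:::all_truth_detected(half, truth, 0.05))
})

test_that("contamination power is bounded and zero under a degenerate cutoff", {
  base <- sim_config(n_subjects = 30, n_markers = 500, sce_specs = list(),
                     noise_sd_range = c(0.2, 0.3),
                     n_passengers = 0, seed = 77)
  pw0 <- contamination_power(c(0.05, 0.2), base, run_params = list(E = 30),
                             alpha = 0, n_reps = 1, seed = 79)
  expect_identical(pw0$power, c(0, 0))
  expect_identical(pw0$sd, c(0.05, 0.2))
})
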