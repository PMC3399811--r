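test_that("carrier counts and event geometry follow the configuration", {
  cfg <- sim_config(n_subjects = 40, n_markers = 1500,
                    sce_specs = list(sce_spec(0.585, 200, 0.15),
                                     sce_spec(1, 100, 0.15),
                                     sce_spec(1.322, 50, 0.15)),
                    seed = 31)
  sim <- simulate_cohort(cfg)
  expect_identical(lengths(sim$truth$carrier_sets), rep(6L, 3))  # round(0.15 * 40)
  iv <- sim$truth$sce_intervals
  expect_identical(iv$end - iv$start + 1L, c(200L, 100L, 50L))
  # non-overlapping with the guard gap
  o <- order(iv$start)
  expect_true(all(iv$start[o][-1] - iv$end[o][-3] > 100))
  expect_identical(sum(sim$truth$marker_labels), 350L)
})

test_that("the mixture formula is exact in the noiseless limits", {
  # no contamination, no noise: a carrier reads the pure-tumour ratio
  cfg <- sim_config(n_subjects = 5, n_markers = 300,
                    sce_specs = list(sce_spec(1, 50, 1)),
                    noise_sd_range = c(0, 0),
                    normal_fraction = normal_fraction_none(),
                    n_passengers = 0, seed = 32)
  sim <- simulate_cohort(cfg)
  iv <- sim$truth$sce_intervals
  inside <- iv$start[1]:iv$end[1]
  expect_equal(unname(sim$data$values[1, inside]), rep(1, 50))
  expect_true(all(sim$data$values[, -inside] == 0))

  # 50% contamination of a 4-copy event: log2((2 + 1) / 2) = 0.585
  expect_equal(tagcna:::mixed_log2_ratio(4, 0.5), log2(1.5), tolerance = 1e-12)
  expect_equal(round(tagcna:::mixed_log2_ratio(4, 0.5), 3), 0.585)

  # gains are compressed toward 0 as contamination rises; losses rise
  p <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(tagcna:::mixed_log2_ratio(4, p)) < 0))
  expect_true(all(diff(tagcna:::mixed_log2_ratio(1, p)) > 0))

  # no passengers, no noise, no contamination, no events: exactly zero
  null0 <- simulate_cohort(sim_config(n_subjects = 3, n_markers = 100,
                                      sce_specs = list(),
                                      noise_sd_range = c(0, 0),
                                      normal_fraction = normal_fraction_none(),
                                      n_passengers = 0, seed = 33))
  expect_true(all(null0$data$values == 0))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- sim_config(n_subjects = 10, n_markers = 400,
                    sce_specs = list(sce_spec(1, 60, 0.2)),
                    passenger_length_range = c(10, 40), seed = 34)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$truth$sce_intervals, b$truth$sce_intervals)
  cfg2 <- cfg; cfg2$seed <- 35
  expect_false(identical(simulate_cohort(cfg2)$data$values, a$data$values))
})

test_that("perfect-signal thresholding recovers the truth for carriers", {
  cfg <- sim_config(n_subjects = 12, n_markers = 600,
                    sce_specs = list(sce_spec(0.585, 80, 0.25),
                                     sce_spec(-1, 60, 0.25)),
                    noise_sd_range = c(0, 0),
                    normal_fraction = normal_fraction_none(),
                    n_passengers = 1, passenger_length_range = c(10, 30),
                    seed = 36)
  sim <- simulate_cohort(cfg)
  calls <- split_by_threshold(sim$data, 0.1, -0.1)
  iv <- sim$truth$sce_intervals
  for (s in 1:2) {
    cm <- if (iv$polarity[s] == "amp") calls$amp else calls$del
    inside <- iv$start[s]:iv$end[s]
    for (n in seq_len(12)) {
      carrier <- n %in% sim$truth$carrier_sets[[s]]
      expect_identical(unname(all(cm$values[n, inside] != 0)), carrier)
    }
  }
  # non-event, non-passenger markers are never aberrant
  for (n in seq_len(12)) {
    pass <- sim$truth$passenger_intervals[[n]]
    bg <- setdiff(seq_len(600),
                  c(which(sim$truth$marker_labels),
                    unlist(Map(seq, pass$start, pass$end))))
    expect_true(all(sim$data$values[n, bg] == 0))
  }
})

test_that("null cohorts are event-free and have no enriched locus", {
  cfg <- sim_config(n_subjects = 200, n_markers = 500, sce_specs = list(),
                    passenger_length_range = c(5, 25), seed = 37)
  sim <- simulate_null_cohort(cfg)
  expect_length(sim$truth$carrier_sets, 0L)
  expect_false(any(sim$truth$marker_labels))

  # aggregate passenger coverage per marker stays inside a 99.9% binomial
  # envelope around the mean rate (flatness of the background generator)
  cover <- matrix(FALSE, 200, 500)
  for (n in 1:200) {
    pass <- sim$truth$passenger_intervals[[n]]
    for (r in seq_len(nrow(pass))) cover[n, pass$start[r]:pass$end[r]] <- TRUE
  }
  freq <- colSums(cover)
  # interior markers only: coverage is structurally lower within one
  # passenger length of the chromosome ends
  interior <- 26:475
  rate <- mean(cover[, interior])
  hi <- qbinom(0.9995, 200, rate)
  lo <- qbinom(0.0005, 200, rate)
  expect_true(all(freq[interior] <= hi))
  expect_true(all(freq[interior] >= lo))

  expect_error(simulate_null_cohort(sim_config(seed = 1)), "no consensus")
})

test_that("contamination sweeps vary only the normal-fraction model", {
  base <- sim_config(n_subjects = 15, n_markers = 600,
                     sce_specs = list(),
                     passenger_length_range = c(10, 40), seed = 38)
  sweep <- simulate_contamination_sweep(c(0.1, 0.35), base)
  expect_length(sweep, 2L)
  for (s in sweep) {
    expect_identical(nrow(s$truth$sce_intervals), 2L)
    expect_setequal(s$truth$sce_intervals$polarity, c("amp", "del"))
    expect_identical(lengths(s$truth$carrier_sets), rep(2L, 2))  # round(0.15*15)
    expect_identical(s$config$normal_fraction$mean, 0.6)
  }
  expect_identical(sweep[[1]]$config$normal_fraction$sd, 0.1)
  expect_identical(sweep[[2]]$config$normal_fraction$sd, 0.35)
  # same seed, same placement: cohorts differ only through the fractions
  expect_identical(sweep[[1]]$truth$sce_intervals, sweep[[2]]$truth$sce_intervals)

  # truncated gaussian draws centre on the requested mean
  draws <- withr::with_seed(39, vapply(seq_len(10000), function(i)
    tagcna:::draw_normal_fraction(normal_fraction_gaussian(0.6, 0.1)),
    numeric(1)))
  expect_lt(abs(mean(draws) - 0.6), 3 * 0.1 / sqrt(10000))
  expect_true(all(draws >= 0 & draws <= 0.99))
})

test_that("infeasible event placement is rejected", {
  expect_error(sim_config(n_subjects = 5, n_markers = 100,
                          sce_specs = list(sce_spec(1, 80, 0.5),
                                           sce_spec(1, 40, 0.5))),
               "exceeds")
  cfg <- sim_config(n_subjects = 5, n_markers = 320,
                    sce_specs = list(sce_spec(1, 100, 0.5),
                                     sce_spec(1, 100, 0.5)),
                    n_passengers = 0, guard_gap = 150, seed = 40)
  expect_error(simulate_cohort(cfg), "cannot fit|could not place")
})
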