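test_that("thresholding splits a matrix into amp and del calls with inclusive bounds", {
  rm <- mk_ratio(rbind(c(0.9, -0.8, 0.05), c(0.848, -0.737, -0.7)))
  calls <- split_by_threshold(rm, 0.848, -0.737)
  expect_equal(unname(calls$amp$values[1, ]), c(0.9, 0, 0))
  expect_equal(unname(calls$del$values[1, ]), c(0, -0.8, 0))
  # cells exactly at the thresholds are retained
  expect_equal(unname(calls$amp$values[2, ]), c(0.848, 0, 0))
  expect_equal(unname(calls$del$values[2, ]), c(0, -0.737, 0))

  zero <- split_by_threshold(mk_ratio(matrix(0, 3, 4)), 0.1, -0.1)
  expect_true(all(zero$amp$values == 0))
  expect_true(all(zero$del$values == 0))

  expect_error(split_by_threshold(rm, -0.5, -0.7), "positive")
  expect_error(split_by_threshold(rm, 0.5, 0.7), "negative")
})

test_that("tag scores sum aberration magnitudes across subjects", {
  expect_equal(score_tags(matrix(c(0.5, 0, 1.0), ncol = 1)), 1.5)
  expect_equal(score_tags(matrix(c(-0.8, -0.5), ncol = 1)), 1.3)

  v <- matrix(withr::with_seed(3, rnorm(20 * 5)), 20, 5)
  want <- vapply(1:5, function(m) {
    acc <- 0
    for (n in 1:20) acc <- acc + abs(v[n, m])
    acc
  }, numeric(1))
  expect_equal(unname(score_tags(v)), want, tolerance = 1e-12)

  # a score is zero iff its column is entirely zero
  v[, 2] <- 0
  s <- score_tags(v)
  expect_identical(unname(s == 0), c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("permutation preserves each row's multiset and is uniform", {
  one <- tag_matrix(matrix(c(1, 2, 3), ncol = 1))
  expect_identical(permute_tags(one, seed = 1)$values, one$values)

  tm <- tag_matrix(rand_call_values(8, 6, prob = 0.5, seed = 14))
  pm <- permute_tags(tm, seed = 2)
  for (n in 1:8)
    expect_equal(sort(pm$values[n, ]), sort(tm$values[n, ]))
  # score totals are conserved under permutation
  expect_equal(sum(score_tags(pm)), sum(score_tags(tm)), tolerance = 1e-12)

  # uniformity over the 6 arrangements of a 3-column row
  tm2 <- tag_matrix(rbind(c(1, 2, 3), c(4, 5, 6)))
  draws <- withr::with_seed(90, {
    vapply(seq_len(10000), function(e)
      paste(permute_tags(tm2)$values[1, ], collapse = ","), character(1))
  })
  freq <- table(draws) / 10000
  expect_length(freq, 6L)
  se <- sqrt((1 / 6) * (5 / 6) / 10000)
  expect_true(all(abs(freq - 1 / 6) <= 3 * se))
})

test_that("null distribution maxima behave in degenerate cases", {
  zero <- tag_matrix(matrix(0, 5, 4))
  D <- null_distribution(zero, E = 25, seed = 3)
  expect_identical(D$maxima, rep(0, 25))

  # one subject: a row permutation cannot change the row's max magnitude
  single <- tag_matrix(matrix(c(0.5, -1, 0, 2), nrow = 1))
  D1 <- null_distribution(single, E = 40, seed = 4)
  expect_identical(D1$maxima, rep(2, 40))
})

test_that("p-values follow the right-tail indicator convention", {
  D <- c(1, 2, 3)
  expect_equal(p_values(2.5, D), 1 / 3)
  expect_equal(p_values(0, D), 1)
  expect_equal(p_values(4, D), 0)
  expect_equal(p_values(4, D, add_one = TRUE), 1 / 4)
  # ties sit in the rejection count (>= in the indicator)
  expect_equal(p_values(2, D), 2 / 3)
  expect_error(p_values(1, numeric()), "empty")
})

test_that("score ordering is never inverted by p-values", {
  set.seed(55)
  for (rep in 1:20) {
    tm <- tag_matrix(rand_call_values(10, 7, prob = 0.4, seed = rep))
    res <- peel_off(tm, E = 60, alpha = 0.05, seed = 100 + rep)
    o <- order(res$scores)
    expect_true(all(diff(res$p_values[o]) <= 1e-12))
  }
})

test_that("peel-off terminates and reports iteration traces", {
  zero <- tag_matrix(matrix(0, 6, 5))
  res <- peel_off(zero, E = 30, alpha = 0.05, seed = 5)
  expect_identical(res$H, 1L)
  expect_equal(res$p_values, rep(1, 5))
  expect_identical(res$removed_at, integer(5))

  # an overwhelming consensus column is peeled first, then nothing else
  v <- matrix(0, 20, 10)
  v[, 4] <- 2
  res2 <- peel_off(tag_matrix(v), E = 50, alpha = 0.05, seed = 6)
  expect_identical(res2$removed_at[4], 1L)
  expect_identical(res2$H, 2L)
  expect_identical(sum(res2$removed_at > 0), 1L)
  expect_equal(res2$p_values[4], 0)          # D_2 is all-zero, score is 40
  expect_true(all(res2$distributions[[2]] == 0))
  expect_lt(res2$dist_means[2], res2$dist_means[1])

  # alpha = 0 never removes anything
  res3 <- peel_off(tag_matrix(rand_call_values(5, 4, seed = 2)), E = 20,
                   alpha = 0, seed = 7)
  expect_identical(res3$H, 1L)
  expect_identical(res3$removed_at, integer(4))

  # H can never exceed M + 1
  expect_lte(res2$H, ncol(v) + 1L)
})

test_that("the weakest tag always keeps p = 1, so peeling never empties the matrix", {
  # the permuted maximum is at least the mean column score, which is at
  # least the minimum observed score; even an aggressive cutoff leaves a tag
  set.seed(88)
  for (rep in 1:10) {
    tm <- tag_matrix(rand_call_values(8, 5, prob = 0.6, seed = 200 + rep))
    res <- peel_off(tm, E = 40, alpha = 0.9, seed = 300 + rep)
    expect_true(any(res$removed_at == 0))
    weakest <- which.min(res$scores)
    expect_equal(res$p_values[weakest], 1)
  }
})

test_that("significant tags map to block-spanning regions", {
  part <- tagcna:::new_block_partition(c(1L, 6L), c(5L, 12L), c(3L, 9L))
  vals <- cbind(c(1.2, 0, 0.9, 1.1), c(0, 0, 0, 0))
  tm <- tag_matrix(vals, part, "amp")
  mk <- mk_map(12, pos = seq(1000, 50000, length.out = 12))
  res <- list(p_values = c(0.001, 0.8), scores = score_tags(tm))
  out <- call_sces(res, tm, mk, alpha = 0.05)
  expect_identical(nrow(out), 1L)
  expect_equal(out$start_pos, 1000)
  expect_equal(out$end_pos, mk$pos[5])
  expect_identical(out$n_subjects_aberrant, 3L)
  expect_identical(out$polarity, "amp")

  none <- call_sces(list(p_values = c(0.9, 0.9), scores = c(0, 0)), tm, mk,
                    alpha = 0.05)
  expect_identical(nrow(none), 0L)
})
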