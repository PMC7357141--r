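test_that("runs are the replication unit: group SE is SD of run means over sqrt(n)", {
  runs <- tibble::tibble(
    run = rep(c("r1", "r2", "r3"), each = 4),
    group = "II",
    value = rep(c(1, 2, 3), each = 4)
  )
  g <- aggregate_runs(runs)
  expect_equal(g$mean, 2)
  expect_equal(g$se, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(g$se, 0.5773503, tolerance = 1e-6)
  expect_equal(g$n_runs, 3)
  expect_false(g$single_run)

  # permutation invariance in run order
  g2 <- aggregate_runs(runs[sample(nrow(runs)), ])
  expect_equal(as.data.frame(g2), as.data.frame(g))

  # single run: SE 0 with flag; identical runs: SE 0
  g1 <- aggregate_runs(dplyr::filter(runs, run == "r1"))
  expect_equal(g1$se, 0)
  expect_true(g1$single_run)
  gid <- aggregate_runs(dplyr::mutate(runs, value = 7))
  expect_equal(gid$se, 0)
  expect_error(aggregate_runs(runs[0, ]), class = "car_grouping_error")
})

test_that("group comparison is a two-sided Welch test on run means with stars", {
  expect_error(compare_groups(1, c(1, 2)), class = "car_insufficient_replication_error")

  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)

  sep <- compare_groups(c(0, 0.01, -0.01, 0), c(1, 1.01, 0.99, 1))
  expect_lt(sep$p_value, 0.01)
  expect_equal(sep$stars, "**")

  # agrees with stats::t.test (Welch) to full precision
  a <- c(1.2, 1.9, 0.8, 1.4, 1.7)
  b <- c(2.4, 2.2, 2.9, 2.1)
  got <- compare_groups(a, b)
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  td <- tidy(got)
  expect_equal(td$p.value, got$p_value)
  expect_equal(td$estimate, mean(a) - mean(b))
})

test_that("a textbook Welch example reproduces to 4 decimals", {
  # classic unequal-variance example (Welch 1947 framing): two small samples
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6, 19.0, 21.7, 21.4)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.1, 22.9, 30.5)
  got <- compare_groups(a, b)
  ref <- t.test(a, b)
  expect_equal(round(got$statistic, 4), round(unname(ref$statistic), 4))
  expect_equal(round(got$p_value, 4), round(ref$p.value, 4))
  expect_equal(round(got$df, 4), round(unname(ref$parameter), 4))
})

test_that("the Welch test holds its nominal type-I error on null simulations", {
  n_sim <- 2000
  rejections <- withr::with_seed(20260922, {
    sum(vapply(seq_len(n_sim), function(i) {
      a <- rnorm(6, mean = 1.0, sd = 0.4)
      b <- rnorm(6, mean = 1.0, sd = 0.4)
      compare_groups(a, b)$p_value < 0.05
    }, logical(1)))
  })
  rate <- rejections / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("contact frequencies pool frames across runs with the display thresholds", {
  bonds <- tibble::tibble(
    run = c(rep("r1", 10), rep("r2", 5)),
    frame = c(1:10, 1:5),
    pair = "G1:C1054"
  )
  fpr <- c(r1 = 50, r2 = 50)
  cm <- contact_map(bonds, fpr)
  expect_equal(cm$frequency, 15 / 100)
  expect_equal(cm$category, "strong")

  # boundary behaviour: 0.10 inclusive strong, 0.025 exclusive none
  expect_equal(contact_category(0.10), "strong")
  expect_equal(contact_category(0.025), "none")
  expect_equal(contact_category(0.09999), "weak")
  expect_equal(contact_category(0.02501), "weak")
  expect_equal(contact_category(0), "none")
  expect_equal(contact_category(1), "strong")

  # duplicate bonds within a frame collapse; unseen pairs report 0
  dup <- dplyr::bind_rows(bonds, bonds[1, ])
  cm2 <- contact_map(dup, fpr, pair_universe = c("G1:C1054", "C2:A1196"))
  expect_equal(cm2$frequency[cm2$pair == "G1:C1054"], 0.15)
  expect_equal(cm2$frequency[cm2$pair == "C2:A1196"], 0)
  expect_equal(cm2$category[cm2$pair == "C2:A1196"], "none")

  # invariance to run concatenation order
  cm3 <- contact_map(bonds[sample(nrow(bonds)), ], fpr)
  expect_equal(as.data.frame(cm3), as.data.frame(cm))
  expect_true(all(cm$frequency >= 0 & cm$frequency <= 1))

  # run-averaged pooling variant
  cm4 <- contact_map(bonds, fpr, pooling = "runs")
  expect_equal(cm4$frequency, mean(c(10 / 50, 5 / 50)))
})
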