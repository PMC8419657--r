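make_hm <- function(values) {
  # wrap a plain matrix as a heat_matrix for unit tests
  ends <- as.Date("2020-01-08") + 10 * (seq_len(ncol(values)) - 1)
  colnames(values) <- format(ends, "%Y-%m-%d")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("item%02d", seq_len(nrow(values)))
  structure(list(values = values,
                 schedule = tibble::tibble(index = seq_along(ends),
                                           start = as.Date("2019-12-30"),
                                           end = ends, valid = TRUE),
                 min_occurrence = 2, normalization = "sum",
                 threshold_when = "before"),
            class = "heat_matrix")
}

test_that("window minima match a brute-force column scan", {
  m <- rbind(c(5, 1, 4), c(7.5, 2, 3), c(6, 9, 0.5))
  expect_equal(unname(window_minima(make_hm(m))), c(5, 1, 0.5))
  expect_equal(unname(window_minima(make_hm(matrix(7.5, 1, 1)))), 7.5)
  set.seed(1)
  r <- matrix(runif(60), 10, 6)
  r[sample(60, 12)] <- NA
  r[1, ] <- 0.001   # keep every column observed
  hm <- make_hm(r)
  expect_equal(unname(window_minima(hm)),
               apply(r, 2, min, na.rm = TRUE))
  bad <- make_hm(rbind(c(1, NA), c(2, NA)))
  expect_error(window_minima(bad), "no observed")
})

test_that("imputation draws stay inside the central mass of the minima", {
  # minima 1..16 planted as one fully observed row; one row all-missing
  vals <- rbind(1:16, NA * 1:16, 2 * (1:16))
  hm <- make_hm(vals)
  qs <- quantile(1:16, c(0.05, 0.95))
  draws <- replicate(50, {
    comp <- impute_heat(hm, central_mass = 0.90, seed = sample.int(1e6, 1))
    comp[2, ]
  })
  expect_true(all(draws >= qs[1] & draws <= qs[2]))
  expect_gt(length(unique(as.vector(draws))), 100)    # genuinely random draws

  # observed cells untouched; determinism under a fixed seed
  c1 <- impute_heat(hm, seed = 7)
  c2 <- impute_heat(hm, seed = 7)
  expect_identical(c1, c2)
  expect_equal(c1[1, ], hm$values[1, ])
  expect_equal(c1[3, ], hm$values[3, ])

  # degenerate: all minima equal -> imputed cells equal that minimum
  flat <- make_hm(rbind(rep(3, 4), c(NA, NA, 4, 5)))
  expect_warning(comp <- impute_heat(flat, seed = 1), "minimum")
  expect_equal(unname(comp[2, 1:2]), c(3, 3))
})

test_that("trend test matches the closed-form example and its conventions", {
  r <- trend_test(c(1, 2, 3), 4)
  expect_equal(r$prior_mean, 2)
  expect_equal(r$se, 1 / sqrt(3))
  expect_equal(r$t, -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$p, pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_lt(r$p, 0.05)

  expect_equal(trend_test(c(1, 2, 3), 2)$p, 0.5)      # current at the prior mean
  deg <- trend_test(c(5, 5, 5), 5)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0.5)
  expect_equal(trend_test(c(5, 5, 5), 9)$p, 0)        # above a zero-spread prior
  expect_equal(trend_test(c(5, 5, 5), 1)$p, 1)

  # right tail mirrors the left tail
  expect_equal(trend_test(c(1, 2, 3), 4, tail = "right")$p,
               1 - trend_test(c(1, 2, 3), 4)$p)
})

test_that("trend test agrees with stats::t.test on random instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    priors <- rnorm(n, sd = runif(1, 0.1, 5))
    current <- rnorm(1)
    got <- trend_test(priors, current)
    ref <- t.test(priors, mu = current, alternative = "less")
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("detection on a fully observed matrix ignores the imputation seed", {
  set.seed(5)
  vals <- matrix(runif(50, 1, 10), 5, 10)
  hm <- make_hm(vals)
  a <- detect_significant_items(hm, seed = 1)
  b <- detect_significant_items(hm, seed = 999, n_iterations = 3)
  expect_equal(a$p, b$p)
  expect_equal(a$t, b$t)
  # eligibility starts at the third valid window
  expect_equal(sort(unique(a$window)), 3:10)
  # left-tail convention: a planted jump in the last window is flagged
  vals2 <- vals
  vals2[1, 10] <- 50
  res <- detect_significant_items(make_hm(vals2), seed = 1)
  expect_true(res$significant[res$item == "item01" & res$window == 10])
  expect_equal(significant_items(res)[1], "item01")
  wc <- window_counts(res)
  expect_equal(sum(wc$n_significant), sum(res$significant))
})

test_that("imputation averaging is reproducible and spans iterations", {
  vals <- rbind(c(NA, NA, 2, 3, 4, 5), c(1, 1.5, 2, 2.5, 3, 3.5),
                c(4, 4, 4, 4, 4, 4))
  hm <- make_hm(vals)
  r1 <- detect_significant_items(hm, seed = 42)
  r2 <- detect_significant_items(hm, seed = 42)
  expect_identical(r1$p, r2$p)
  r3 <- detect_significant_items(hm, seed = 43)
  expect_false(identical(r1$p, r3$p))
  comp <- completed_heat(r1)
  expect_equal(comp[2, ], hm$values[2, ])             # observed rows untouched
  expect_false(anyNA(comp))
})

test_that("robustness correlation is 1 for identical schemes and bounded otherwise", {
  corp <- generate_corpus(n_docs = 800, seed = 21)
  same <- robustness_correlation(corp$documents, "2019-12-30", "2020-01-28",
                                 "2020-06-26", step_a = 10, step_b = 10,
                                 n_iterations = 2, seed = 3)
  expect_true(all(abs(same$r - 1) < 1e-12, na.rm = TRUE))
  rc <- robustness_correlation(corp$documents, "2019-12-30", "2020-01-28",
                               "2020-06-26", step_a = 10, step_b = 20,
                               n_iterations = 2, seed = 3)
  expect_true(all(rc$r >= -1 & rc$r <= 1, na.rm = TRUE))
  expect_gte(nrow(rc), 6)
})
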