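test_that("row Z-scoring has the closed form and flags constant rows", {
  z <- zscore_rows(rbind(a = c(1, 2, 3), b = c(4, 4, 4)))
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(attr(z, "constant_items"), "b")

  set.seed(8)
  r <- matrix(rnorm(80, mean = 3, sd = 7), 8, 10,
              dimnames = list(letters[1:8], NULL))
  zr <- zscore_rows(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(zr, 1, sd)), rep(1, 8), tolerance = 1e-12)
})

test_that("average-linkage merges match the brute-force agglomerator", {
  # 4 colinear points at positions 0, 1, 3, 17 along direction (0.6, 0.8):
  # a,b merge first (d=1), then c joins at mean(3,2)=2.5, then d at
  # mean(17,16,14)=47/3
  pos <- c(a = 0, b = 1, c = 3, d = 17)
  x <- cbind(1 + 0.6 * pos, 0.8 * pos)
  rownames(x) <- names(pos)
  model <- cluster_items(x, k = 2)
  expect_equal(unname(model$assignment[c("a", "b", "c", "d")]), c(1, 1, 1, 2))
  expect_equal(model$tree$height[1], 1)
  expect_equal(model$tree$height[2], 2.5)

  parts <- bf_average_partitions(x[order(rownames(x)), ])
  for (k in c(3, 2, 1)) {
    got <- cutree(model$tree, k = k)
    ref <- parts[[nrow(x) - k]]
    expect_equal(canonical_partition(unname(got)), canonical_partition(ref))
  }

  # random instances: partitions agree at every cut level
  set.seed(12)
  for (rep in 1:5) {
    y <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(letters[1:7], NULL))
    tree <- cluster_items(y, k = 2)$tree
    ref_parts <- bf_average_partitions(y[order(rownames(y)), ])
    for (k in 2:6) {
      expect_equal(canonical_partition(unname(cutree(tree, k))),
                   canonical_partition(ref_parts[[7 - k]]))
    }
  }
})

test_that("clustering recovers planted monotone-up vs monotone-down shapes", {
  skip_if_not_installed("mclust")
  set.seed(77)
  up <- t(replicate(8, seq(0, 1, length.out = 12) + rnorm(12, sd = 0.05)))
  down <- t(replicate(8, seq(1, 0, length.out = 12) + rnorm(12, sd = 0.05)))
  m <- rbind(up, down)
  rownames(m) <- sprintf("i%02d", 1:16)
  model <- cluster_items(zscore_rows(m), k = 2)
  truth <- rep(1:2, each = 8)
  ari <- mclust::adjustedRandIndex(model$assignment[sprintf("i%02d", 1:16)], truth)
  expect_equal(ari, 1)
})

test_that("degenerate rows are excluded and k is validated", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(5, 5, 5))
  z <- zscore_rows(m)
  expect_message(model <- cluster_items(z, k = 2), "constant")
  expect_equal(sort(names(model$assignment)), c("a", "b"))
  expect_equal(model$dropped, "c")
  expect_error(cluster_items(z, k = 5), "exceeds")
  singles <- cluster_items(zscore_rows(rbind(a = c(1, 2), b = c(2, 1))), k = 2)
  expect_equal(length(unique(singles$assignment)), 2)
})

test_that("clustering is invariant to item order and per-row affine scaling", {
  set.seed(31)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(letters[1:10], NULL))
  p1 <- cluster_items(zscore_rows(m), k = 3)$assignment
  shuffled <- m[sample(nrow(m)), ]
  p2 <- cluster_items(zscore_rows(shuffled), k = 3)$assignment
  expect_equal(p1[sort(names(p1))], p2[sort(names(p2))])
  # affine rescaling of raw rows disappears under Z-scoring
  scaled <- m * runif(10, 0.5, 20) + rnorm(10)
  p3 <- cluster_items(zscore_rows(scaled), k = 3)$assignment
  expect_equal(canonical_partition(unname(p1[letters[1:10]])),
               canonical_partition(unname(p3[letters[1:10]])))
})

test_that("cluster mean curves are member averages", {
  z <- rbind(a = c(-1, 0, 1), b = c(1, 0, -1), c = c(-1, 0, 1))
  model <- structure(list(assignment = c(a = 1L, b = 1L, c = 2L),
                          z = z, k = 2), class = "heat_clusters")
  mc <- mean_curves(model)
  expect_equal(unname(mc["1", ]), c(0, 0, 0))   # mirror images cancel
  expect_equal(unname(mc["2", ]), unname(z["c", ]))
  set.seed(4)
  zr <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
  asg <- setNames(rep(1:2, 4), letters[1:8])
  mr <- mean_curves(structure(list(assignment = asg, z = zr, k = 2),
                              class = "heat_clusters"))
  expect_equal(unname(mr["1", ]),
               unname(colMeans(zr[names(asg)[asg == 1], ])))
})

test_that("rising waves are maximal strictly increasing runs, ranked by rise", {
  dates <- as.Date("2020-01-08") + 10 * (0:5)
  w <- rising_waves(c(0, 1, 2, 1, 2, 3), dates)
  expect_equal(w$start_window, c(1, 4))
  expect_equal(w$end_window, c(3, 6))
  expect_equal(w$start, dates[c(1, 4)])
  expect_equal(w$end, dates[c(3, 6)])

  mono <- rising_waves(seq(0, 1, length.out = 6), dates)
  expect_equal(nrow(mono), 1)
  expect_equal(mono$start_window, 1)
  expect_equal(mono$end_window, 6)

  expect_equal(nrow(rising_waves(seq(1, 0, length.out = 6), dates)), 0)

  # ranking: with max_waves = 1 only the largest total rise survives
  curve <- c(0, 0.2, 0.1, 0.15, 2, 1.5)
  top <- rising_waves(curve, dates, max_waves = 1)
  expect_equal(top$start_window, 3)
  expect_equal(top$rise, 1.9)
})

test_that("wave detection locates a planted change point on a cluster curve", {
  dates <- as.Date("2020-01-08") + 10 * (0:15)
  for (cp in c(6, 9, 12)) {
    # small pre-change oscillation, then a clear sustained rise at window cp
    pre <- 0.03 * rep(c(1, -1), length.out = cp)
    curve <- c(pre, seq(0.3, 2, length.out = 16 - cp))
    w <- rising_waves(curve, dates, max_waves = 1)
    expect_lte(abs(w$start_window - cp), 1)
  }
})
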