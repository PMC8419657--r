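test_that("counting rules: thresholding, links, and total link strength", {
  docs <- toy_corpus(list(c("a", "b"), c("a", "b", "c"), "a"))
  net2 <- build_network(docs, min_occurrence = 2)
  expect_equal(net2$items, c("a", "b"))
  expect_equal(net2$links$weight, 2)                 # link(a,b) = 2 documents
  expect_equal(unname(net2$tls[c("a", "b")]), c(2, 2))

  net1 <- build_network(docs, min_occurrence = 1)
  expect_equal(unname(net1$tls[c("a", "b", "c")]), c(3, 3, 2))

  # three identical documents {x,y,z}: every pair co-occurs 3 times
  docs3 <- toy_corpus(rep(list(c("x", "y", "z")), 3))
  net3 <- build_network(docs3, min_occurrence = 2)
  expect_equal(unname(net3$tls), rep(6, 3))

  # repeated keywords within a record count once
  dup <- toy_corpus(list(c("a", "a", "b"), c("a", "b")))
  expect_equal(unname(build_network(dup, 2)$tls), c(2, 2))

  empty <- build_network(toy_corpus(list())[0, ], 2)
  expect_length(empty$items, 0)
})

test_that("network counts match a brute-force pair counter on random corpora", {
  vocab <- c("aged", "child", "anxiety", "pregnancy", "quarantine", "phylogeny")
  for (seed in 1:8) {
    kws <- random_kw_list(25, vocab, seed, k_range = c(1, 5))
    docs <- toy_corpus(kws)
    for (mo in c(1, 2, 3)) {
      got <- build_network(docs, min_occurrence = mo)
      ref <- bf_network(kws, min_occ = mo)
      expect_equal(got$items, ref$items)
      expect_equal(unname(got$occurrence), unname(ref$occurrence))
      expect_equal(unname(got$tls), unname(ref$tls))
      expect_equal(got$links, ref$links)
      # row-sum identity: total tls is twice the total link weight
      expect_equal(sum(got$tls), 2 * sum(got$links$weight))
    }
    # threshold-after mode keeps links to dropped items in the tls
    got_a <- build_network(docs, min_occurrence = 2, threshold_when = "after")
    ref_a <- bf_network(kws, min_occ = 2, threshold_when = "after")
    expect_equal(unname(got_a$tls), unname(ref_a$tls))
  }
})

test_that("percentage normalization sums to 100 and handles degenerate cases", {
  docs <- toy_corpus(list(c("a", "b"), c("a", "b")))
  pct <- normalize_tls(build_network(docs, 2))
  expect_equal(unname(pct), c(50, 50))

  docs3 <- toy_corpus(rep(list(c("x", "y", "z")), 3))
  expect_equal(unname(normalize_tls(build_network(docs3, 2))),
               rep(100 / 3, 3))

  # isolated items above threshold: all-zero tls warns and returns zeros
  iso <- toy_corpus(list("a", "a", "b", "b"))
  expect_warning(pct0 <- normalize_tls(build_network(iso, 2)), "zero")
  expect_equal(unname(pct0), c(0, 0))

  # max normalization scales the strongest item to 100
  mx <- normalize_tls(build_network(toy_corpus(list(c("a", "b"), c("a", "b"),
                                                    c("a", "c"), c("a", "c"))), 2),
                      mode = "max")
  expect_equal(max(mx), 100)
})

test_that("percentages are scale-free and raw counts grow with the window", {
  vocab <- letters[1:8]
  kws <- random_kw_list(20, vocab, 3, k_range = c(2, 5))
  docs <- toy_corpus(kws)
  pct1 <- normalize_tls(build_network(docs, 2))
  doubled <- toy_corpus(c(kws, kws))
  pct2 <- normalize_tls(build_network(doubled, 2))
  expect_equal(pct1, pct2[names(pct1)])

  sched <- mark_valid(build_schedule("2020-01-01", "2020-01-05", 5, "2020-01-20"),
                      docs)
  nets <- lapply(seq_len(nrow(sched)), function(i) {
    build_network(docs[docs$pub_date <= sched$end[i], ], 1)
  })
  for (i in 2:length(nets)) {
    shared <- intersect(nets[[i - 1]]$items, nets[[i]]$items)
    expect_true(all(nets[[i]]$occurrence[shared] >= nets[[i - 1]]$occurrence[shared]))
    expect_true(all(nets[[i]]$tls[shared] >= nets[[i - 1]]$tls[shared]))
  }
})

test_that("heat matrix equals hand-computed values on a toy split corpus", {
  # window 1 (through Jan 10): docs {a,b}, {a,b}; window 2 adds {a,c}, {b,c}, {a,b,c}
  docs <- toy_corpus(list(c("a", "b"), c("a", "b"), c("a", "c"), c("b", "c"),
                          c("a", "b", "c")),
                     dates = as.Date(c("2020-01-02", "2020-01-05", "2020-01-12",
                                       "2020-01-15", "2020-01-18")))
  sched <- mark_valid(build_schedule("2020-01-01", "2020-01-10", 10, "2020-01-20"),
                      docs)
  hm <- assemble_heat_matrix(docs, sched, min_occurrence = 2)
  # window 1: only link a-b (2 docs) -> tls a=2, b=2 -> 50/50, c missing
  expect_equal(unname(hm$values[c("a", "b"), 1]), c(50, 50))
  expect_true(is.na(hm$values["c", 1]))
  # window 2 by hand: link(a,b)=3, link(a,c)=2, link(b,c)=2
  # tls: a=5, b=5, c=4 -> total 14
  expect_equal(unname(hm$values[, 2]), 100 * c(5, 5, 4) / 14)
})

test_that("an item first reaching the threshold mid-horizon is masked before", {
  dates <- as.Date("2020-01-01") + 0:19
  kws <- c(rep(list(c("a", "b")), 10),
           rep(list(c("a", "b", "q")), 10))
  docs <- toy_corpus(kws, dates = dates)
  sched <- mark_valid(build_schedule("2020-01-01", "2020-01-05", 5, "2020-01-20"),
                      docs)
  hm <- assemble_heat_matrix(docs, sched, min_occurrence = 2)
  expect_true(all(is.na(hm$values["q", as.Date(colnames(hm$values)) < "2020-01-12"])))
  expect_true(all(!is.na(hm$values["q", as.Date(colnames(hm$values)) >= "2020-01-15"])))
  expect_true(all(!is.na(hm$values["a", ])))    # present throughout
  expect_error(assemble_heat_matrix(docs, sched[0, ], 2), "valid")
})
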