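test_that("efficient subset is the m consecutive pairs plus (1, m)", {
  expect_equal(efficient_pairs(4),
               cbind(a = c(1L, 2L, 3L, 1L), b = c(2L, 3L, 4L, 4L)),
               ignore_attr = TRUE)
  p4 <- efficient_pairs(4)
  key <- paste(p4[, 1], p4[, 2])
  expect_false(any(c("1 3", "2 4") %in% key))  # excluded pairs
  expect_equal(efficient_pairs(2), cbind(a = 1L, b = 2L),
               ignore_attr = TRUE)
  expect_equal(nrow(efficient_pairs(10)), 10)       # vs 45 all pairs
  expect_equal(nrow(tsabc:::all_pairs(10)), 45)
  expect_error(efficient_pairs(1), ">= 2")
})

test_that("worked-example partition has the documented structure", {
  ts <- fixture_fig2()
  seg12 <- mrca_partition(ts, c(1, 2))
  expect_equal(seg12$l, c(1L, 43L))
  expect_equal(seg12$r, c(42L, 100L))
  expect_equal(seg12$mrca, c(6L, 8L))
  seg34 <- mrca_partition(ts, c(3, 4))
  expect_equal(nrow(seg34), 1L)
  expect_equal(c(seg34$l, seg34$r, seg34$mrca), c(1L, 100L, 5L))
  seg41 <- mrca_partition(ts, c(4, 1))
  expect_equal(nrow(seg41), 1L)
  expect_equal(c(seg41$l, seg41$r), c(1L, 100L))
  expect_error(mrca_partition(ts, c(2, 2)), "distinct")
})

test_that("partition equals the per-site MRCA oracle on random instances", {
  set.seed(515)
  for (i in 1:12) {
    ts <- random_treeseq(m = sample(2:8, 1), seq_len = sample(20:300, 1))
    pr <- if (ts$m == 2) cbind(1, 2) else
      rbind(efficient_pairs(ts$m)[sample(ts$m, 2), , drop = FALSE])
    for (k in seq_len(nrow(pr))) {
      got <- mrca_partition(ts, pr[k, ])
      exp <- partition_oracle(ts, pr[k, ])
      expect_equal(as.data.frame(got), exp, ignore_attr = TRUE)
    }
  }
})

test_that("per-pair segments partition the genome, in (c1, c2, l) order", {
  set.seed(626)
  for (i in 1:8) {
    ts <- random_treeseq()
    seg <- extract_ibd(ts, pairs = "all")
    # partition: lengths sum to seq_len for every pair, no overlaps
    by_pair <- split(seg, paste(seg$c1, seg$c2))
    for (s in by_pair) {
      expect_equal(sum(s$r - s$l + 1), ts$seq_len)
      expect_true(all(s$l[-1] == s$r[-nrow(s)] + 1))
      # adjacent segments have different MRCA
      if (nrow(s) > 1) expect_true(all(diff(s$mrca) != 0))
    }
    expect_false(is.unsorted(seg$c1))
    o <- order(seg$c1, seg$c2, seg$l)
    expect_equal(o, seq_len(nrow(seg)))
  }
})

test_that("length threshold is strict and monotone", {
  ts <- fixture_fig2()
  # [1,42] has length 42 <= 50: only [43,100] survives
  seg <- extract_ibd(ts, pairs = cbind(1, 2), threshold = 50)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$l, seg$r), c(43L, 100L))
  # a segment exactly at the threshold is excluded (strict comparison)
  expect_equal(nrow(extract_ibd(ts, pairs = cbind(1, 2), threshold = 42)),
               1L)
  expect_equal(nrow(extract_ibd(ts, pairs = cbind(1, 2), threshold = 41)),
               2L)
  set.seed(737)
  for (i in 1:5) {
    ts <- random_treeseq()
    thr <- c(0, 10, 50, 200)
    counts <- lengths <- numeric(length(thr))
    for (j in seq_along(thr)) {
      s <- extract_ibd(ts, pairs = "all", threshold = thr[j])
      counts[j] <- nrow(s)
      lengths[j] <- sum(s$r - s$l + 1)
    }
    expect_true(all(diff(counts) <= 0))
    expect_true(all(diff(lengths) <= 0))
  }
})

test_that("per-segment mismatch counts equal a direct haplotype recount", {
  set.seed(848)
  for (i in 1:8) {
    ts <- random_treeseq()
    h <- to_haplotypes(ts)
    seg <- extract_ibd(ts, pairs = "all", haplotypes = h,
                       mismatch_sites = TRUE)
    for (k in sample(nrow(seg), min(20, nrow(seg)))) {
      a <- seg$c1[k]; b <- seg$c2[k]
      in_seg <- h$positions >= seg$l[k] & h$positions <= seg$r[k]
      expected <- sum(h$mat[a, in_seg] != h$mat[b, in_seg])
      expect_equal(seg$n_mismatch[k], expected)
      sites <- seg$mismatch_sites[[k]]
      expect_true(all(sites >= seg$l[k] & sites <= seg$r[k]))
      expect_equal(length(sites), expected)
    }
  }
})

test_that("efficient subsets cover every edge; restricted sets need not", {
  ts <- fixture_fig2()
  expect_true(edge_coverage_check(ts)$ok)
  res <- edge_coverage_check(ts, pairs = cbind(1, 2))
  expect_false(res$ok)
  # the edges above leaves 3 and 4 cannot be on a (1,2) descent path
  expect_true(all(c(3, 4) %in% res$uncovered$child))
  set.seed(959)
  for (i in 1:30) {
    ts <- random_treeseq(m = sample(3:10, 1))
    expect_true(edge_coverage_check(ts)$ok)
  }
})

test_that("IBD TSV export has the documented columns", {
  seg <- extract_ibd(fixture_fig2())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ibd(seg, path)
  back <- read.delim(path)
  expect_equal(names(back),
               c("c1", "c2", "l", "r", "mrca", "n_mismatch", "tmrca"))
  expect_equal(back$l, seg$l)
  expect_true(all(is.na(back$tmrca)))  # rank-order-only fixture
})
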