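test_that("constructor enforces the tree-sequence invariants", {
  ed <- data.frame(child = 1:2, parent = c(3L, 3L), left = 1L, right = 10L)
  expect_s3_class(tree_seq(2, 10, ed), "tree_seq")
  # coordinates out of range
  bad <- ed; bad$right[1] <- 11L
  expect_error(tree_seq(2, 10, bad), "left <= right <= seq_len")
  bad <- ed; bad$left[1] <- 0L
  expect_error(tree_seq(2, 10, bad), "left <= right <= seq_len")
  # time ordering by id
  bad <- data.frame(child = c(1L, 3L), parent = c(3L, 2L), left = 1L,
                    right = 10L)
  expect_error(tree_seq(3, 10, bad), "parent id")
  # two parents over overlapping intervals
  bad <- data.frame(child = c(1L, 1L, 2L), parent = c(3L, 4L, 3L),
                    left = c(1L, 5L, 1L), right = c(10L, 10L, 10L))
  expect_error(tree_seq(2, 10, bad), "two parents")
  # mismatch record outside the genome
  expect_error(tree_seq(2, 10, ed,
                        mutations = data.frame(node = 1L, site = 11L)),
               "site out of range")
})

test_that("the four-leaf worked example has the documented structure", {
  ts <- fixture_fig2()
  expect_equal(ts$m, 4L)
  expect_equal(ts$seq_len, 100L)
  expect_equal(sort(unique(c(ts$edges$parent))), 5:8)
  expect_true(check_paths(ts))
  # MRCA of (1,2) changes from node 6 to node 8 between sites 42 and 43
  expect_equal(site_mrca_oracle(ts, 1, 2, 42L), 6L)
  expect_equal(site_mrca_oracle(ts, 1, 2, 43L), 8L)
})

test_that("text container round-trips edge and mismatch tables exactly", {
  set.seed(101)
  for (i in 1:5) {
    ts <- random_treeseq()
    path <- withr::local_tempfile(fileext = ".tstxt")
    write_treeseq(ts, path)
    ts2 <- read_treeseq(path)
    expect_identical(ts2$edges, ts$edges)
    expect_identical(ts2$mutations, ts$mutations)
    expect_identical(ts2$m, ts$m)
    expect_identical(ts2$seq_len, ts$seq_len)
  }
  # node times survive too
  ed <- data.frame(child = 1:2, parent = 3L, left = 1L, right = 10L)
  ts <- tree_seq(2, 10, ed, node_times = c(0, 0, 12.5))
  path <- withr::local_tempfile(fileext = ".tstxt")
  write_treeseq(ts, path)
  expect_equal(read_treeseq(path)$node_times, c(0, 0, 12.5))
})

test_that("binary .trees container round-trips through the bridge", {
  ts <- fixture_suite()[["three-breakpoint-m4"]]$ts
  trees <- withr::local_tempfile(fileext = ".trees")
  save_trees(ts, trees)
  ts2 <- load_treeseq(trees)
  expect_identical(ts2$edges[order(ts2$edges$child, ts2$edges$left), ],
                   ts$edges[order(ts$edges$child, ts$edges$left), ],
                   ignore_attr = TRUE)
  expect_equal(ts2$m, ts$m)
  # and the text path is auto-detected as well
  txt <- withr::local_tempfile(fileext = ".tstxt")
  write_treeseq(ts, txt)
  expect_identical(load_treeseq(txt)$edges, ts$edges)
})

test_that("haplotypes equal the site-by-site path-parity oracle", {
  ed <- data.frame(child = 1:2, parent = 3L, left = 1L, right = 10L)
  ts <- tree_seq(2, 10, ed)
  expect_equal(ncol(to_haplotypes(ts)$mat), 0L)  # empty M -> all ancestral

  ts <- tree_seq(2, 10, ed, mutations = data.frame(node = 1L, site = 7L))
  h <- to_haplotypes(ts)
  expect_equal(h$positions, 7L)
  expect_equal(h$mat[, 1], c(1L, 0L))  # singleton by construction

  set.seed(202)
  for (i in 1:10) {
    ts <- random_treeseq()
    h <- to_haplotypes(ts)
    oracle <- haplotype_oracle(ts)
    expect_equal(h$positions, oracle$pos)
    expect_equal(unname(h$mat), unname(oracle$G))
  }
})

test_that("per-site leaf-to-root paths are unique on random instances", {
  set.seed(303)
  for (i in 1:10) {
    ts <- random_treeseq(seq_len = sample(20:200, 1))
    expect_true(check_paths(ts))
  }
})

test_that("VCF export/import round-trips variant haplotypes", {
  set.seed(404)
  mat <- matrix(rbinom(6 * 8, 1, 0.4), nrow = 6)
  mat[, 3] <- 0L  # monomorphic: dropped on export
  h <- haplotype_matrix(mat, positions = c(3L, 10L, 17L, 20L, 44L, 60L,
                                           71L, 90L), seq_len = 100L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(h, vcf)
  h2 <- read_vcf_haplotypes(vcf)
  keep <- colSums(h$mat) > 0 & colSums(h$mat) < h$m
  expect_equal(h2$mat, unname(h$mat[, keep]))
  expect_equal(h2$positions, h$positions[keep])
  expect_equal(h2$seq_len, 100L)
})

test_that("HapMap-style genetic maps are parsed into per-site rates", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("position COMBINED_rate(cM/Mb) Genetic_Map(cM)",
               "1000 1.5 0.0015",
               "50000 0.8 0.0405",
               "100000 2.0 0.0805"), path)
  gm <- read_genetic_map(path)
  expect_s3_class(gm, "genetic_map")
  expect_equal(gm$pos, c(1000, 50000, 100000))
  expect_equal(gm$rate, c(1.5, 0.8, 2.0) * 1e-8)
})
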