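#' The four-leaf worked-example tree sequence
#'
#' A hand-built ancestral recombination graph over a genome of 100 sites
#' with leaves \{1,2,3,4\} and ancestral nodes \{5,6,7,8\}, containing one
#' MRCA-changing recombination between sites 42 and 43.  The pair (1,2)
#' has MRCA 6 on `[1,42]` and MRCA 8 on `[43,100]`; the pairs (3,4) and
#' (4,1) keep a single MRCA (5 and 8) across the whole sequence, so a
#' recombination need not change every pair's MRCA.  Node times are not
#' assigned (rank order only), as for an inferred tree sequence.
#'
#' @return a `tree_seq` with `m = 4`, `seq_len = 100`.
#' @export
fixture_fig2 <- function() {
  edges <- data.frame(
    child  = c(3L, 4L, 1L, 2L, 5L, 6L, 2L, 5L, 7L, 1L),
    parent = c(5L, 5L, 6L, 6L, 8L, 8L, 7L, 7L, 8L, 8L),
    left   = c(1L, 1L, 1L, 1L, 1L, 1L, 43L, 43L, 43L, 43L),
    right  = c(100L, 100L, 42L, 42L, 42L, 42L, 100L, 100L, 100L, 100L)
  )
  tree_seq(m = 4, seq_len = 100, edges = edges)
}

#' Deterministic fixture collection
#'
#' Small hand-built tree sequences with their expected IBD partitions
#' stored alongside, for unit testing without any simulator dependency.
#' Each element is a list with `ts`, a 2-column `pairs` matrix, and
#' `expected`, a data frame of the segments `(c1, c2, l, r, mrca)` of
#' those pairs.  Tests re-verify every stored expectation against the
#' per-site MRCA oracle.
#'
#' Fixtures: `fig2` (the worked example), `single-tree-m5` (caterpillar,
#' no recombination: every pair has exactly one segment), `two-leaf-recomb`
#' (two leaves, one MRCA-changing breakpoint), `three-breakpoint-m4`
#' (four marginal trees, including recombinations that change only some
#' pairs' MRCA), and `mutations-m3` (single tree with recurrent mutation;
#' carries `expected_haplotypes`).
#'
#' @return named list of fixtures.
#' @export
fixture_suite <- function() {
  out <- list()

  ts <- fixture_fig2()
  out[["fig2"]] <- list(
    ts = ts, pairs = efficient_pairs(4),
    expected = data.frame(
      c1 = c(1L, 1L, 1L, 2L, 2L, 3L), c2 = c(2L, 2L, 4L, 3L, 3L, 4L),
      l = c(1L, 43L, 1L, 1L, 43L, 1L),
      r = c(42L, 100L, 100L, 42L, 100L, 100L),
      mrca = c(6L, 8L, 8L, 8L, 7L, 5L)))

  # caterpillar over 5 leaves, one tree spanning [1, 50]
  ed <- data.frame(child = c(1L, 2L, 6L, 3L, 7L, 4L, 8L, 5L),
                   parent = c(6L, 6L, 7L, 7L, 8L, 8L, 9L, 9L),
                   left = 1L, right = 50L)
  ts <- tree_seq(5, 50, ed)
  pr <- all_pairs(5)
  mr <- c(6L, 7L, 8L, 9L, 7L, 8L, 9L, 8L, 9L, 9L)  # caterpillar MRCAs
  out[["single-tree-m5"]] <- list(
    ts = ts, pairs = pr,
    expected = data.frame(c1 = pr[, 1], c2 = pr[, 2], l = 1L, r = 50L,
                          mrca = mr))

  # two leaves, MRCA 3 on [1,30] and 4 on [31,60]
  ed <- data.frame(child = c(1L, 2L, 1L, 2L),
                   parent = c(3L, 3L, 4L, 4L),
                   left = c(1L, 1L, 31L, 31L),
                   right = c(30L, 30L, 60L, 60L))
  out[["two-leaf-recomb"]] <- list(
    ts = tree_seq(2, 60, ed), pairs = cbind(a = 1L, b = 2L),
    expected = data.frame(c1 = 1L, c2 = 2L, l = c(1L, 31L),
                          r = c(30L, 60L), mrca = c(3L, 4L)))

  # four marginal trees over [1,50]; breaks at 10/11, 20/21, 35/36.
  # Trees 1 and 4 are identical ((1,2)5,(3,4)6)7; tree 2 regrafts leaf 1
  # under new root 8; tree 3 additionally regrafts leaf 3 under root 9.
  # Some recombinations leave some pairs' MRCA unchanged, e.g. (2,4) has a
  # single segment.
  ed <- data.frame(
    child  = c(2L, 4L, 5L, 6L, 1L, 3L, 1L, 7L, 3L, 8L, 1L, 3L),
    parent = c(5L, 6L, 7L, 7L, 5L, 6L, 8L, 8L, 9L, 9L, 5L, 6L),
    left   = c(1L, 1L, 1L, 1L, 1L, 1L, 11L, 11L, 21L, 21L, 36L, 36L),
    right  = c(50L, 50L, 50L, 50L, 10L, 20L, 35L, 35L, 35L, 35L, 50L, 50L)
  )
  ts <- tree_seq(4, 50, ed)
  expected <- rbind(
    data.frame(c1 = 1L, c2 = 2L, l = c(1L, 11L, 36L),
               r = c(10L, 35L, 50L), mrca = c(5L, 8L, 5L)),
    data.frame(c1 = 1L, c2 = 3L, l = c(1L, 11L, 21L, 36L),
               r = c(10L, 20L, 35L, 50L), mrca = c(7L, 8L, 9L, 7L)),
    data.frame(c1 = 1L, c2 = 4L, l = c(1L, 11L, 36L),
               r = c(10L, 35L, 50L), mrca = c(7L, 8L, 7L)),
    data.frame(c1 = 2L, c2 = 3L, l = c(1L, 21L, 36L),
               r = c(20L, 35L, 50L), mrca = c(7L, 9L, 7L)),
    data.frame(c1 = 2L, c2 = 4L, l = 1L, r = 50L, mrca = 7L),
    data.frame(c1 = 3L, c2 = 4L, l = c(1L, 21L, 36L),
               r = c(20L, 35L, 50L), mrca = c(6L, 9L, 6L)))
  out[["three-breakpoint-m4"]] <- list(ts = ts, pairs = all_pairs(4),
                                       expected = expected)

  # single tree over 3 leaves with mutations, incl. a recurrent hit:
  # site 5 on the external branch of 1; site 9 on node 4 (leaves 1,2);
  # site 15 on node 5 (all leaves) AND again above leaf 1 (parity
  # reverts leaf 1 to ancestral there)
  ed <- data.frame(child = c(1L, 2L, 4L, 3L),
                   parent = c(4L, 4L, 5L, 5L), left = 1L, right = 20L)
  mu <- data.frame(node = c(1L, 4L, 5L, 1L), site = c(5L, 9L, 15L, 15L))
  ts <- tree_seq(3, 20, ed, mutations = mu,
                 node_times = c(0, 0, 0, 1, 2))
  out[["mutations-m3"]] <- list(
    ts = ts, pairs = all_pairs(3),
    expected = data.frame(c1 = c(1L, 1L, 2L), c2 = c(2L, 3L, 3L),
                          l = 1L, r = 20L, mrca = c(4L, 5L, 5L)),
    expected_haplotypes = matrix(
      c(1L, 0L, 0L,   # site 5
        1L, 1L, 0L,   # site 9
        0L, 1L, 1L),  # site 15
      nrow = 3, dimnames = list(NULL, c(5, 9, 15))),
    expected_positions = c(5L, 9L, 15L))
  out
}
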