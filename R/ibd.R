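#' Efficient subset of sequence pairs
#'
#' For `m` ordered sequences, the pairs `(c, c+1)` for `c = 1..m-1`
#' together with `(1, m)`.  The IBD segments of these `m` pairs jointly
#' cover every edge of the tree sequence via a descent path from a
#' segment's MRCA, so no mutation is invisible to the subset, while the
#' number of pairs grows linearly in `m` rather than as `m(m-1)/2`.
#'
#' @param m sample size, at least 2.
#' @return an integer matrix with columns `a`, `b`, one row per pair
#'   (`m` rows for `m >= 3`, one row for `m = 2`).
#' @export
efficient_pairs <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || m < 2) {
    stop("m must be a single integer >= 2")
  }
  m <- as.integer(m)
  p <- cbind(a = 1:(m - 1), b = 2:m)
  if (m >= 3) p <- rbind(p, c(1L, m))
  p
}

all_pairs <- function(m) {
  idx <- utils::combn(m, 2)
  cbind(a = idx[1, ], b = idx[2, ])
}

resolve_pairs <- function(pairs, m) {
  if (is.character(pairs)) {
    pairs <- match.arg(pairs, c("efficient", "all"))
    return(if (pairs == "efficient") efficient_pairs(m) else all_pairs(m))
  }
  p <- as.matrix(pairs)
  if (ncol(p) != 2) stop("pairs must be a 2-column matrix of leaf ids")
  storage.mode(p) <- "integer"
  if (any(p < 1 | p > m)) stop("pair leaf ids out of range 1..", m)
  if (any(p[, 1] == p[, 2])) stop("a pair must contain two distinct leaves")
  t(apply(p, 1, sort))  # normalise a < b
}

#' Partition the genome into IBD segments for one sequence pair
#'
#' An IBD segment of a pair is a maximal genome interval over which the
#' pair shares a single most recent common ancestor (MRCA) node.  With no
#' length threshold the segments of a pair partition `[1, seq_len]`;
#' segment boundaries occur exactly where the pair's MRCA node changes,
#' which is not at every recombination (a recombination may leave the MRCA
#' unchanged).  A change of MRCA node identity breaks a segment even when
#' the two nodes have equal age: the definition is node-based.
#'
#' @param ts a `tree_seq`.
#' @param pair integer vector of two distinct leaf ids.
#' @return a data frame with columns `c1`, `c2`, `l`, `r`, `mrca`, ordered
#'   by `l`.
#' @export
mrca_partition <- function(ts, pair) {
  stopifnot(length(pair) == 2)
  if (pair[1] == pair[2]) stop("a pair must contain two distinct leaves")
  p <- resolve_pairs(matrix(as.integer(pair), 1), ts$m)
  seg <- cpp_ibd_segments(ts$n_nodes, ts$seq_len,
                          ts$edges$child, ts$edges$parent,
                          ts$edges$left, ts$edges$right,
                          p[, 1], p[, 2])
  data.frame(c1 = p[1, 1], c2 = p[1, 2], l = seg$l, r = seg$r,
             mrca = seg$mrca)
}

#' Extract IBD segments for a set of sequence pairs
#'
#' Runs the MRCA partition for every pair, attaches per-segment mismatch
#' counts (sites in `[l, r]` at which the two sequences differ) and, when
#' node times are known, the segment TMRCA in generations.  An optional
#' length threshold retains only segments strictly longer than `threshold`
#' sites; thresholding is a form of data reduction and the standard
#' protocol applies it with `pairs = "all"` rather than the efficient
#' subset.
#'
#' @param ts a `tree_seq`.
#' @param pairs `"efficient"` (default), `"all"`, or a 2-column matrix of
#'   leaf ids.
#' @param threshold retain only segments with `r - l + 1 > threshold`
#'   (strict); 0 keeps everything.
#' @param haplotypes optional precomputed [to_haplotypes()] result, to
#'   avoid recomputation; mismatch counts are computed from sequence
#'   differences, which handles repeat mutation on one lineage.
#' @param mismatch_sites also return the per-segment sets of mismatching
#'   site positions as a list column.
#' @return a data frame of class `"ibd_segments"` with columns `c1`, `c2`,
#'   `l`, `r`, `mrca`, `n_mismatch`, `tmrca` (NA when node times are
#'   unknown), ordered by `(c1, c2, l)`.  Attribute `seq_len` records the
#'   genome length.
#' @export
extract_ibd <- function(ts, pairs = "efficient", threshold = 0,
                        haplotypes = NULL, mismatch_sites = FALSE) {
  stopifnot(threshold >= 0)
  p <- resolve_pairs(pairs, ts$m)
  seg <- cpp_ibd_segments(ts$n_nodes, ts$seq_len,
                          ts$edges$child, ts$edges$parent,
                          ts$edges$left, ts$edges$right,
                          p[, 1], p[, 2])
  out <- data.frame(c1 = p[seg$pair, 1], c2 = p[seg$pair, 2],
                    l = seg$l, r = seg$r, mrca = seg$mrca)
  # mismatch counts from sequence differences
  if (is.null(haplotypes)) haplotypes <- to_haplotypes(ts)
  out$n_mismatch <- 0L
  if (mismatch_sites) out$mismatch_sites <- vector("list", nrow(out))
  if (length(haplotypes$positions)) {
    g <- haplotypes$mat
    pos <- haplotypes$positions
    for (i in seq_len(nrow(p))) {
      rows <- which(seg$pair == i)
      if (!length(rows)) next
      dpos <- pos[g[p[i, 1], ] != g[p[i, 2], ]]
      if (!length(dpos)) next
      idx <- findInterval(dpos, seg$l[rows])
      cnt <- tabulate(idx, nbins = length(rows))
      out$n_mismatch[rows] <- cnt
      if (mismatch_sites) {
        out$mismatch_sites[rows] <- split(dpos, factor(idx, 1:length(rows)))
      }
    }
  }
  out$tmrca <- ts$node_times[out$mrca]
  o <- order(out$c1, out$c2, out$l)
  out <- out[o, , drop = FALSE]
  if (threshold > 0) {
    out <- out[out$r - out$l + 1 > threshold, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "seq_len") <- ts$seq_len
  attr(out, "n_pairs") <- nrow(p)
  class(out) <- c("ibd_segments", "data.frame")
  out
}

#' Check efficient-subset edge coverage
#'
#' Verifies that every edge of the tree sequence lies, over some part of
#' its genome interval, on a descent path from the MRCA of at least one
#' IBD segment of the given pairs down to one of the pair's leaves.  This
#' is the defining property of an efficient subset: it guarantees that
#' every mutation is visible in at least one pair's mismatch set.
#'
#' @param ts a `tree_seq`.
#' @param pairs as in [extract_ibd()].
#' @return a list with elements `ok` (logical) and `uncovered` (data frame
#'   of uncovered edges, empty when `ok`).
#' @export
edge_coverage_check <- function(ts, pairs = "efficient") {
  p <- resolve_pairs(pairs, ts$m)
  cov <- cpp_edge_coverage(ts$n_nodes, ts$seq_len,
                           ts$edges$child, ts$edges$parent,
                           ts$edges$left, ts$edges$right,
                           p[, 1], p[, 2])
  list(ok = all(cov), uncovered = ts$edges[!cov, , drop = FALSE])
}

#' @export
print.ibd_segments <- function(x, ...) {
  cat(sprintf("IBD segments: %d segments over %d pair(s), seq_len %d\n",
              nrow(x), length(unique(paste(x$c1, x$c2))),
              attr(x, "seq_len")))
  NextMethod()
}

#' Write IBD segments as TSV
#'
#' Columns `c1, c2, l, r, mrca, n_mismatch, tmrca` (empty when unknown).
#'
#' @param segments an `ibd_segments` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ibd <- function(segments, path) {
  df <- as.data.frame(segments)[
    , c("c1", "c2", "l", "r", "mrca", "n_mismatch", "tmrca")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
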