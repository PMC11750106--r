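#' Haplotype matrix
#'
#' Binary haplotypes for `m` sequences over a genome of `seq_len` sites,
#' with 0 denoting the ancestral allele.  Only columns at recorded
#' (potentially variant) positions are stored; all other sites are
#' implicitly ancestral for every sequence.
#'
#' @param mat integer matrix, `m` rows (sequences) by `length(positions)`
#'   columns, values in \{0, 1\}.
#' @param positions 1-based site positions of the columns, strictly
#'   increasing.
#' @param seq_len genome length in sites.
#' @return an object of class `"haplotype_matrix"`.
#' @export
haplotype_matrix <- function(mat, positions, seq_len) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  positions <- as.integer(positions)
  stopifnot(ncol(mat) == length(positions),
            !is.unsorted(positions, strictly = TRUE) || !length(positions),
            all(mat %in% c(0L, 1L)),
            !length(positions) || (positions[1] >= 1 &&
                                     positions[length(positions)] <= seq_len))
  structure(list(mat = mat, positions = positions,
                 seq_len = as.integer(seq_len), m = nrow(mat)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "Haplotype matrix: %d sequences, %d sites (%d variant columns stored)\n",
    x$m, x$seq_len, length(x$positions)))
  invisible(x)
}

#' Materialise haplotypes from a tree sequence
#'
#' The derived state of leaf `c` at site `s` is 1 iff an odd number of
#' mismatch records lie on the path from `c` to the root at `s` (so a
#' repeat mutation on one lineage reverts the allele).
#'
#' @param ts a `tree_seq`.
#' @param drop_monomorphic drop columns at which all leaves carry the same
#'   state (possible after repeat mutation).
#' @return a [haplotype_matrix()].
#' @export
to_haplotypes <- function(ts, drop_monomorphic = FALSE) {
  mu <- ts$mutations
  if (!nrow(mu)) {
    return(haplotype_matrix(matrix(0L, ts$m, 0), integer(0), ts$seq_len))
  }
  gt <- cpp_genotypes(ts$m, ts$n_nodes, ts$seq_len,
                      ts$edges$child, ts$edges$parent,
                      ts$edges$left, ts$edges$right,
                      mu$node, mu$site)
  h <- haplotype_matrix(gt$G, gt$pos, ts$seq_len)
  if (drop_monomorphic) {
    dc <- colSums(h$mat)
    keep <- dc > 0L & dc < h$m
    h <- haplotype_matrix(h$mat[, keep, drop = FALSE], h$positions[keep],
                          h$seq_len)
  }
  h
}

#' Inject sequencing errors into haplotypes
#'
#' Each (sequence, site) entry over the full genome is independently set to
#' the derived state 1 with probability `eps`; entries already derived are
#' unchanged.  Errors at previously monomorphic sites create new stored
#' columns.
#'
#' @param h a [haplotype_matrix()].
#' @param eps per-site error rate, in `[0, 0.01]`.
#' @param seed optional integer seed (local RNG stream).
#' @return a new `haplotype_matrix`.
#' @export
inject_errors <- function(h, eps, seed = NULL) {
  stopifnot(eps >= 0, eps <= 1e-2)
  if (eps == 0) return(h)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n_cells <- as.numeric(h$m) * h$seq_len
  k <- stats::rbinom(1, n_cells, eps)
  if (k == 0) return(h)
  cells <- sample_cells(k, h$m, h$seq_len)
  err_sites <- sort(unique(cells$site))
  all_pos <- sort(unique(c(h$positions, err_sites)))
  mat <- matrix(0L, h$m, length(all_pos))
  mat[, match(h$positions, all_pos)] <- h$mat
  mat[cbind(cells$row, match(cells$site, all_pos))] <- 1L
  haplotype_matrix(mat, all_pos, h$seq_len)
}

# sample k distinct cells uniformly from an m x seq_len grid
sample_cells <- function(k, m, seq_len) {
  n_cells <- as.numeric(m) * seq_len
  # rejection for duplicates; k << n_cells in all intended uses
  idx <- unique(floor(stats::runif(k) * n_cells))
  while (length(idx) < k) {
    idx <- unique(c(idx, floor(stats::runif(k - length(idx)) * n_cells)))
  }
  idx <- idx[seq_len(k)]
  list(row = as.integer(idx %% m) + 1L,
       site = as.integer(idx %/% m) + 1L)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Remove sites with high minor allele count
#'
#' Sites whose folded minor-allele count (the smaller of the derived and
#' ancestral allele counts) exceeds `max_count` are removed.  Used to
#' discard old variants before demographic inference of the recent past;
#' must be applied identically to observed and simulated data.
#'
#' @param h a [haplotype_matrix()].
#' @param max_count largest minor-allele count retained.
#' @return a filtered `haplotype_matrix`.  Idempotent.
#' @export
filter_mac <- function(h, max_count) {
  stopifnot(max_count >= 1)
  if (!length(h$positions)) return(h)
  dc <- colSums(h$mat)
  minor <- pmin(dc, h$m - dc)
  keep <- minor <= max_count
  haplotype_matrix(h$mat[, keep, drop = FALSE], h$positions[keep], h$seq_len)
}

#' Export haplotypes as phased biallelic VCF
#'
#' Writes one haploid sample column per sequence with phased-style GT
#' coding (`0` ancestral, `1` derived).  Monomorphic stored columns are
#' dropped, matching the usual VCF restriction to variant sites.
#'
#' @param h a [haplotype_matrix()].
#' @param path output `.vcf` path.
#' @param chrom chromosome label for the CHROM column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(h, path, chrom = "1") {
  dc <- colSums(h$mat)
  keep <- which(dc > 0L & dc < h$m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, h$seq_len),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", seq_len(h$m))), collapse = "\t")
  ), con)
  for (j in keep) {
    writeLines(paste(c(chrom, h$positions[j], ".", "A", "T", ".", "PASS",
                       "AA=A", "GT", h$mat[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read phased haplotypes from a VCF file
#'
#' Reads a phased biallelic VCF into a binary haplotype matrix with 0 for
#' the ancestral (REF) allele.  Diploid phased genotypes (`a|b`) are split
#' into two haploid sequences per sample; haploid `GT` values are taken
#' as-is.
#'
#' @param path a `.vcf` file.
#' @param seq_len genome length; defaults to the largest contig length
#'   declared in the header, or the last variant position.
#' @return a [haplotype_matrix()].
#' @export
read_vcf_haplotypes <- function(path, seq_len = NULL) {
  hdr <- character()
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) break
    if (startsWith(ln, "##")) {
      hdr <- c(hdr, ln)
    } else if (startsWith(ln, "#CHROM")) {
      cols <- strsplit(ln, "\t")[[1]]
      break
    } else stop("malformed VCF header")
  }
  close(con)
  body <- data.table::fread(path, skip = "#CHROM", sep = "\t",
                            header = TRUE, data.table = FALSE)
  names(body) <- cols
  if (is.null(seq_len)) {
    lens <- regmatches(hdr, regexec("contig=.*length=([0-9]+)", hdr))
    lens <- suppressWarnings(as.integer(vapply(
      lens, function(x) if (length(x) == 2) x[2] else NA_character_, "")))
    seq_len <- if (any(!is.na(lens))) max(lens, na.rm = TRUE) else
      max(body$POS)
  }
  gt_cols <- cols[-(1:9)]
  gts <- as.matrix(body[, gt_cols, drop = FALSE])
  storage.mode(gts) <- "character"
  split_gt <- function(x) {
    parts <- strsplit(x, "[|/]")
    as.integer(unlist(parts))
  }
  per_sample <- lapply(seq_along(gt_cols), function(j) {
    v <- split_gt(gts[, j])
    k <- length(v) / max(1, nrow(body))
    matrix(v, nrow = k)  # k haplotypes x sites
  })
  mat <- do.call(rbind, per_sample)
  haplotype_matrix(mat, body$POS, seq_len)
}
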