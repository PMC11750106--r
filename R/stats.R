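#' Summary statistics from IBD segments
#'
#' The four statistics driving the ABC engine:
#' \describe{
#'   \item{total_mismatch}{total mismatch count over the segments,
#'     \eqn{\bar M \times I = \sum_i |M_i|} — the mean mismatches per
#'     segment times the segment count.}
#'   \item{c1}{genome-wide singleton count: sites at which exactly one of
#'     the `m` sequences carries the derived allele.  Inflated by
#'     sequencing error, which is what makes `eps` identifiable.}
#'   \item{mean_len, sd_len}{mean and standard deviation of the IBD
#'     segment lengths `r_i - l_i` (as printed; not `+ 1`), carrying the
#'     demographic signal.}
#' }
#' The mismatch pair informs `mu`/`eps`; the length pair informs
#' demographic parameters; all four are used for joint inference.
#'
#' @param segments an [extract_ibd()] result (at least one segment).
#' @param haplotypes a [haplotype_matrix()]; required only when `c1` is in
#'   the mask.
#' @param mask character vector naming the active components.
#' @return a named numeric vector of class `"summary_stats"` with
#'   attribute `mask`.  `mean_len`/`sd_len` over fewer than 2 segments are
#'   flagged by an `NA` `sd_len`.
#' @export
compute_stats <- function(segments, haplotypes = NULL,
                          mask = c("total_mismatch", "c1", "mean_len",
                                   "sd_len")) {
  mask <- match.arg(mask, several.ok = TRUE)
  if (!nrow(segments)) stop("empty segment set")
  out <- c(total_mismatch = NA_real_, c1 = NA_real_, mean_len = NA_real_,
           sd_len = NA_real_)
  if ("total_mismatch" %in% mask) {
    out["total_mismatch"] <- sum(segments$n_mismatch)
  }
  if ("c1" %in% mask) {
    if (is.null(haplotypes)) {
      stop("haplotypes are required to compute the singleton count c1")
    }
    out["c1"] <- singleton_count(haplotypes)
  }
  len <- segments$r - segments$l
  if ("mean_len" %in% mask) out["mean_len"] <- mean(len)
  if ("sd_len" %in% mask) {
    out["sd_len"] <- if (nrow(segments) >= 2) stats::sd(len) else NA_real_
  }
  out <- out[mask]
  structure(out, mask = mask, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

# pooled stats over a multi-chromosome dataset: mismatch and singleton
# counts add; lengths pool across chromosomes
compute_stats_pooled <- function(seg_list, hap_list, mask) {
  lens <- unlist(lapply(seg_list, function(s) s$r - s$l))
  n_seg <- length(lens)
  out <- c(total_mismatch = NA_real_, c1 = NA_real_, mean_len = NA_real_,
           sd_len = NA_real_)
  if ("total_mismatch" %in% mask) {
    out["total_mismatch"] <- sum(vapply(
      seg_list, function(s) sum(s$n_mismatch), 0))
  }
  if ("c1" %in% mask) {
    out["c1"] <- sum(vapply(hap_list, singleton_count, 0L))
  }
  if ("mean_len" %in% mask) out["mean_len"] <- mean(lens)
  if ("sd_len" %in% mask) {
    out["sd_len"] <- if (n_seg >= 2) stats::sd(lens) else NA_real_
  }
  structure(out[mask], mask = mask, class = "summary_stats")
}

#' Serialise summary statistics as one TSV row
#'
#' Appends (or creates) a reference-table file with one row per dataset.
#'
#' @param stats a [compute_stats()] result, or a matrix/data frame of rows.
#' @param path output path.
#' @param append append to an existing table.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path, append = FALSE) {
  df <- if (is.matrix(stats) || is.data.frame(stats)) {
    as.data.frame(stats)
  } else {
    as.data.frame(as.list(unclass(stats)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append,
                     append = append)
  invisible(path)
}
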