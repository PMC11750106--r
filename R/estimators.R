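#' Method-of-moments estimation of mutation and error rates
#'
#' Given IBD segments with known TMRCAs (a tree sequence with node times),
#' solves two moment equations.  To leading order, the total pairwise
#' mismatch count \eqn{T = \sum_i |M_i|} has expectation
#' \eqn{2\mu \sum_i g_i L_i + 2\epsilon \sum_i L_i} (each segment's two
#' lineages accumulate mutations over `2 g_i L_i` site-generations, and
#' each leaf contributes error flips at rate `eps` per site), while the
#' genome-wide singleton count \eqn{C_1} has expectation
#' \eqn{\mu X + \epsilon m \ell}, with \eqn{X} the external branch length
#' of the tree sequence integrated over sites (a mutation is a singleton
#' iff it falls on an edge whose child is a leaf).  Here `L_i = r_i - l_i
#' + 1` counts the sites of segment `i`.
#'
#' With `order = "second"` (the default) the expectations carry the
#' second-order correction terms that matter at realistic scales, under
#' the parity semantics of mismatch records: per-site mismatch
#' probability \eqn{(\lambda_i - \lambda_i^2)(1 - 4\epsilon(1-\epsilon)) +
#' 2\epsilon(1-\epsilon)} with \eqn{\lambda_i = 2\mu g_i} (recurrent
#' mutation and error/mutation cancellation), and singleton expectation
#' \eqn{\mu X (1 - m\epsilon) + m\ell\epsilon(1 - (m-1)\epsilon)}
#' (an error at an already-singleton site destroys it; two errors at one
#' site make a doubleton).  The mildly nonlinear system is solved by
#' fixed-point iteration from the linear solution.  `order = "first"`
#' keeps the pure linearisation, which inverts a generative model with
#' mismatches placed at exactly rate \eqn{2\mu g} per site.  Estimates
#' are truncated at 0.
#'
#' @param segments an [extract_ibd()] result with non-`NA` `tmrca`.
#' @param ts the generating `tree_seq` (for external branch spans and the
#'   singleton count); must carry node times.
#' @param haplotypes optional precomputed [to_haplotypes()] result.
#' @param order `"second"` (default) or `"first"`, see Details.
#' @return an object of class `"mm_fit"`: list with `mu`, `eps`, and the
#'   moment summaries used.  `coef()` returns `c(mu, eps)`.
#' @export
mm_estimate <- function(segments, ts, haplotypes = NULL,
                        order = c("second", "first")) {
  order <- match.arg(order)
  if (!nrow(segments)) stop("no IBD segments supplied")
  if (anyNA(segments$tmrca)) {
    stop("all segments need a TMRCA; the tree sequence must carry node times")
  }
  L <- segments$r - segments$l + 1
  T_mm <- sum(segments$n_mismatch)
  A <- sum(segments$tmrca * L)
  A2 <- sum(segments$tmrca^2 * L)
  B <- sum(L)
  if (is.null(haplotypes)) haplotypes <- to_haplotypes(ts)
  c1 <- singleton_count(haplotypes)
  ext <- ts$edges$child <= ts$m
  span <- ts$edges$right - ts$edges$left + 1
  X <- sum(span[ext] * ts$node_times[ts$edges$parent[ext]])
  # total branch length integrated over sites: the mutation opportunity;
  # an error creates a new singleton only at a not-already-variant site
  br <- ts$node_times[ts$edges$parent] - ts$node_times[ts$edges$child]
  W <- sum(span * br)
  m <- ts$m
  ml <- as.numeric(m) * ts$seq_len
  solve_mm <- function(mu_k, eps_k) {
    if (order == "first") {
      M <- rbind(c(2 * A, 2 * B), c(X, ml))
    } else {
      e4 <- 1 - 4 * eps_k * (1 - eps_k)
      ce <- 1 - (m - 1) * eps_k
      M <- rbind(c((2 * A - 4 * mu_k * A2) * e4, 2 * (1 - eps_k) * B),
                 c(X * (1 - m * eps_k) - W * m * eps_k * ce, ml * ce))
    }
    if (abs(det(M)) < .Machine$double.eps * max(abs(M))^2) {
      stop("singular moment system (are all TMRCAs zero?)")
    }
    solve(M, c(T_mm, c1))
  }
  est <- solve_mm(0, 0)  # linear start
  if (order == "second") {
    for (it in 1:25) {
      new <- solve_mm(max(est[1], 0), max(min(est[2], 0.5), 0))
      if (all(abs(new - est) <= 1e-12 * pmax(abs(est), 1e-300))) {
        est <- new
        break
      }
      est <- new
    }
  }
  structure(list(mu = max(est[1], 0), eps = max(est[2], 0),
                 moments = list(total_mismatch = T_mm, c1 = c1,
                                sum_gL = A, sum_g2L = A2, sum_L = B,
                                ext_branch_span = X,
                                m = m, seq_len = ts$seq_len),
                 order = order,
                 n_segments = nrow(segments)),
            class = "mm_fit")
}

#' @export
coef.mm_fit <- function(object, ...) c(mu = object$mu, eps = object$eps)

#' @export
print.mm_fit <- function(x, ...) {
  cat("Method-of-moments rate estimates (from", x$n_segments,
      "IBD segments)\n")
  cat(sprintf("  mu  = %.4g per site per generation\n", x$mu))
  cat(sprintf("  eps = %.4g per site\n", x$eps))
  invisible(x)
}

singleton_count <- function(h) {
  if (!length(h$positions)) return(0L)
  sum(colSums(h$mat) == 1L)
}

#' Per-segment TMRCA estimate
#'
#' Inverts the segment mismatch expectation: with mismatch fraction
#' `|M|/L`, the estimate is `(|M|/L - 2 eps) / (2 mu)`, floored at
#' `g_floor` generations to avoid degenerate values for mismatch-free
#' short segments.  Monotone non-decreasing in the mismatch count and
#' non-increasing in `L * mu`.
#'
#' @param segments an [extract_ibd()] result (or any data frame with
#'   columns `l`, `r`, `n_mismatch`).
#' @param mu mutation rate per site per generation (> 0).
#' @param eps sequencing error rate per site.
#' @param g_floor lower bound in generations (default 1).
#' @return numeric vector of TMRCA estimates, one per segment.
#' @export
estimate_tmrca <- function(segments, mu, eps = 0, g_floor = 1) {
  stopifnot(mu > 0, g_floor > 0)
  L <- segments$r - segments$l + 1
  pmax((segments$n_mismatch / L - 2 * eps) / (2 * mu), g_floor)
}

#' Nonparametric population-size curve from pair TMRCAs
#'
#' For a pair of sequences the coalescence hazard at generation `g` is
#' `1/N(g)`, so with `f` the density of pair TMRCAs and `F` its integral,
#' `N(g) = (1 - F(g)) / f(g)`.  The density is estimated by a Gaussian
#' kernel on log-transformed TMRCAs (they span orders of magnitude) with
#' Silverman's bandwidth by default, and the curve is truncated where the
#' estimated `F` exceeds `f_max` (tail estimates are unstable).
#'
#' @param tmrcas positive TMRCA estimates (e.g. [estimate_tmrca()] pooled
#'   over the segments of many pairs).
#' @param grid generations at which to report the curve; defaults to a
#'   geometric grid over the central mass of the sample.
#' @param bw bandwidth for [stats::density()] on the log scale.
#' @param f_max truncate the curve where the estimated CDF exceeds this.
#' @return an object of class `"popsize_curve"`: data frame columns `g`,
#'   `N`, with attributes `bandwidth`, `n`, `reliable`.
#' @export
estimate_popsize <- function(tmrcas, grid = NULL, bw = "nrd0",
                             f_max = 0.99) {
  tmrcas <- tmrcas[is.finite(tmrcas) & tmrcas > 0]
  if (!length(tmrcas)) stop("no (positive, finite) TMRCA values supplied")
  if (length(tmrcas) < 100) {
    warning("fewer than 100 TMRCA values; the curve will be noisy")
  }
  lg <- log(tmrcas)
  if (stats::sd(lg) == 0) {
    warning("degenerate TMRCA sample (all values equal); curve unreliable")
    out <- data.frame(g = unique(tmrcas), N = NA_real_)
    return(structure(out, bandwidth = NA_real_, n = length(tmrcas),
                     reliable = FALSE,
                     class = c("popsize_curve", "data.frame")))
  }
  den <- stats::density(lg, bw = bw, n = 2048, cut = 4)
  dx <- diff(den$x[1:2])
  cdf <- cumsum(den$y) * dx
  cdf <- cdf / max(cdf)
  if (is.null(grid)) {
    qs <- stats::quantile(tmrcas, c(0.002, 0.995))
    grid <- exp(seq(log(qs[1]), log(qs[2]), length.out = 200))
  }
  lgd <- log(grid)
  f_log <- stats::approx(den$x, den$y, xout = lgd, rule = 2)$y
  F_g <- stats::approx(den$x, cdf, xout = lgd, rule = 2)$y
  keep <- F_g <= f_max & f_log > 0
  out <- data.frame(g = grid[keep], N = (1 - F_g[keep]) /
                      (f_log[keep] / grid[keep]))
  structure(out, bandwidth = den$bw, n = length(tmrcas), reliable = TRUE,
            class = c("popsize_curve", "data.frame"))
}

#' @export
print.popsize_curve <- function(x, ...) {
  cat(sprintf(
    "Nonparametric N(g) curve: %d grid points, n = %d, log-bandwidth %.3g%s\n",
    nrow(x), attr(x, "n"), attr(x, "bandwidth"),
    if (isFALSE(attr(x, "reliable"))) "  [UNRELIABLE]" else ""))
  invisible(x)
}

#' @export
plot.popsize_curve <- function(x, log = "xy", ...) {
  graphics::plot(x$g, x$N, type = "l", log = log,
                 xlab = "g (generations ago)", ylab = "N(g)", ...)
  invisible(x)
}

#' Write a population-size curve as TSV
#'
#' @param curve a [estimate_popsize()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popsize <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
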