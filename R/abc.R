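#' Independent uniform priors
#'
#' Per-parameter independent uniform bounds for the ABC engine.
#' Recognised parameter names: `mu`, `eps`, `N`, `N0`, `tau`, `g_star`,
#' `N_star`.  An optional constraint predicate is enforced by rejection at
#' draw time (e.g. the `N(g) <= 2 N0` cap for negative growth is built
#' into the exponential model itself and needs no constraint here).
#'
#' @param ... named length-2 numeric vectors `c(lower, upper)`.
#' @param constraint `NULL`, or `function(theta)` returning `TRUE` for
#'   admissible draws (`theta` a named numeric vector).
#' @return an object of class `"tsabc_prior"`.
#' @export
prior_set <- function(..., constraint = NULL) {
  bounds <- list(...)
  known <- c("mu", "eps", "N", "N0", "tau", "g_star", "N_star")
  if (!length(bounds) || is.null(names(bounds)) || any(names(bounds) == "")) {
    stop("supply named c(lower, upper) bounds")
  }
  bad <- setdiff(names(bounds), known)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || b[1] >= b[2]) {
      stop("prior for ", nm, " must be c(lower, upper) with lower < upper")
    }
  }
  structure(list(bounds = bounds, constraint = constraint),
            class = "tsabc_prior")
}

draw_prior <- function(prior, n) {
  p <- length(prior$bounds)
  draw <- function(k) {
    th <- vapply(prior$bounds, function(b) stats::runif(k, b[1], b[2]),
                 numeric(k))
    matrix(th, nrow = k, dimnames = list(NULL, names(prior$bounds)))
  }
  th <- draw(n)
  if (!is.null(prior$constraint)) {
    ok <- apply(th, 1, prior$constraint)
    while (!all(ok)) {
      th[!ok, ] <- draw(sum(!ok))
      ok <- apply(th, 1, prior$constraint)
    }
  }
  th
}

clip_to_prior <- function(theta, prior) {
  for (nm in colnames(theta)) {
    b <- prior$bounds[[nm]]
    theta[, nm] <- pmin(pmax(theta[, nm], b[1]), b[2])
  }
  theta
}

# substitute inferred parameters into a sim_config template
apply_theta <- function(cfg, theta) {
  nm <- names(theta)
  if ("mu" %in% nm) cfg$mu <- theta[["mu"]]
  if ("eps" %in% nm) cfg$eps <- theta[["eps"]]
  model_par <- intersect(nm, c("N", "N0", "tau", "g_star", "N_star"))
  for (p in model_par) {
    if (is.null(cfg$model[[p]]) && !(p == "tau" &&
                                     cfg$model$kind == "exponential")) {
      stop("parameter ", p, " has no slot in the ", cfg$model$kind,
           " demographic model")
    }
    cfg$model[[p]] <- theta[[p]]
  }
  cfg
}

#' Scaled Euclidean distance between summary-statistic vectors
#'
#' Components are divided by their scale (typically the median absolute
#' deviation across the simulated reference table) before taking the
#' Euclidean norm.  Components with zero scale are dropped with a warning;
#' if every scale is zero the distance falls back to the unscaled
#' Euclidean norm with a warning.
#'
#' @param s,s_obs summary-statistic vectors with identical masks.
#' @param scale positive scale per component.
#' @return a non-negative number.
#' @export
stat_distance <- function(s, s_obs, scale = rep(1, length(s))) {
  stopifnot(length(s) == length(s_obs), length(scale) == length(s))
  if (all(scale == 0)) {
    warning("all statistic scales are zero; using unscaled distance")
    scale <- rep(1, length(s))
  } else if (any(scale == 0)) {
    warning("dropping statistic component(s) with zero scale: ",
            paste(names(s)[scale == 0], collapse = ", "))
    keep <- scale > 0
    s <- s[keep]; s_obs <- s_obs[keep]; scale <- scale[keep]
  }
  sqrt(sum(((s - s_obs) / scale)^2))
}

#' Local-linear regression adjustment of accepted ABC draws
#'
#' Per parameter, a weighted linear regression of the accepted draws on
#' their (centred, scaled) summary statistics; each accepted draw is then
#' shifted to its prediction at the observed statistics:
#' `theta' = theta - b (s - s_obs)`.  Weights are Epanechnikov in the
#' acceptance distance (the classic regression-adjustment scheme); pass
#' `weights = NULL` for unweighted least squares.  Collinear statistics
#' trigger a small ridge penalty with a warning.
#'
#' @param theta matrix of accepted draws (rows) by parameter (columns).
#' @param stats matrix of their summary statistics.
#' @param s_obs observed summary statistics.
#' @param d acceptance distances (used for the Epanechnikov weights).
#' @param scale per-component statistic scales (as used in the distance).
#' @param weights `"epanechnikov"` (default) or `NULL` for unweighted.
#' @return matrix of adjusted draws, same shape as `theta`.
#' @export
linear_adjust <- function(theta, stats, s_obs, d = NULL,
                          scale = rep(1, ncol(stats)),
                          weights = "epanechnikov") {
  theta <- as.matrix(theta)
  stats <- as.matrix(stats)
  k <- nrow(theta)
  if (k <= ncol(stats) + 1) {
    stop("need more accepted draws than statistics + 1")
  }
  scale[scale == 0] <- 1
  Z <- sweep(sweep(stats, 2, s_obs, "-"), 2, scale, "/")
  w <- rep(1, k)
  if (identical(weights, "epanechnikov")) {
    if (is.null(d)) d <- sqrt(rowSums(Z^2))
    delta <- max(d)
    w <- if (delta > 0) pmax(1 - (d / delta)^2, 0) else rep(1, k)
    w[w == 0] <- min(w[w > 0], 1e-6)  # boundary draw keeps tiny weight
  }
  X <- cbind(1, Z)
  XtW <- t(X * w)
  G <- XtW %*% X
  if (rcond(G) < 1e-12) {
    warning("collinear statistics; using ridge fallback in the adjustment")
    G <- G + diag(1e-8 * max(diag(G)), ncol(G))
  }
  B <- solve(G, XtW %*% theta)   # (1 + p_stats) x p_params
  adj <- theta - Z %*% B[-1, , drop = FALSE]
  dimnames(adj) <- dimnames(theta)
  adj
}

default_mask <- function(prior) {
  nm <- names(prior$bounds)
  rate <- any(nm %in% c("mu", "eps"))
  demo <- any(nm %in% c("N", "N0", "tau", "g_star", "N_star"))
  if (rate && demo) c("total_mismatch", "c1", "mean_len", "sd_len")
  else if (rate) c("total_mismatch", "c1")
  else c("mean_len", "sd_len")
}

# stats for one dataset (list of per-chromosome tree_seq or
# haplotype_matrix), shared by the observed and simulated paths
dataset_stats <- function(datasets, backend, pairs, threshold, mask) {
  if (identical(backend, "true-ts")) {
    hs <- lapply(datasets, to_haplotypes)
    segs <- mapply(function(ts, h) {
      extract_ibd(ts, pairs = pairs, threshold = threshold, haplotypes = h)
    }, datasets, hs, SIMPLIFY = FALSE)
  } else {
    hs <- datasets  # haplotype matrices
    segs <- lapply(hs, function(h) {
      extract_ibd(backend(h), pairs = pairs, threshold = threshold,
                  haplotypes = h)
    })
  }
  s <- compute_stats_pooled(segs, hs, mask)
  s[!is.finite(s)] <- 0
  s
}

#' Fit the TSABC model: ABC from tree-sequence IBD statistics
#'
#' The full inference engine.  Summary statistics are computed from the
#' observed data (IBD extraction on the true or inferred tree sequence,
#' then [compute_stats()]); `eta` parameter vectors are drawn from the
#' prior, a dataset is simulated for each under the configured coalescent
#' model, and the same extraction pipeline is applied; the draws whose
#' statistics are closest to the observed ones (scaled Euclidean distance,
#' scales = per-component median absolute deviation across the reference
#' table) are retained and regression-adjusted ([linear_adjust()]).  The
#' posterior mean is the mean of the adjusted retained draws.
#'
#' With `backend = "true-ts"` both the observed and the simulated data are
#' processed from the true tree sequence (with sequencing errors, when
#' `eps` is nonzero, added to the mismatch records at leaf nodes) — the
#' protocol for studies where true IBD is available.  With an inference
#' backend (`"window-upgma"` or a function `haplotypes -> tree_seq`),
#' both sides go through haplotypes, error injection and tree-sequence
#' inference, so the simulation inside ABC mimics the generation process
#' of the data treated as observed.
#'
#' @param observed the observed dataset: a `tree_seq` (or list of them,
#'   one per chromosome) for `backend = "true-ts"`; a
#'   [haplotype_matrix()] (or list) otherwise.
#' @param prior a [prior_set()].
#' @param cfg a [sim_config()] template carrying every fixed parameter
#'   (the inferred ones are overwritten by each draw).
#' @param backend `"true-ts"`, `"window-upgma"`, or a function mapping a
#'   `haplotype_matrix` to a rank-ordered `tree_seq`.
#' @param eta number of simulated datasets (prior draws).
#' @param retain_frac fraction of draws retained (default 1/20).
#' @param mask statistic components to use; defaults to a choice based on
#'   which parameters are inferred (see [compute_stats()]).
#' @param threshold IBD length threshold in sites (strict, 0 = none).  A
#'   positive threshold switches the extraction to all pairs, per the
#'   standard protocol, unless `pairs` is given explicitly.
#' @param pairs pair selection for [extract_ibd()]; default `"efficient"`
#'   for `threshold = 0`, `"all"` otherwise.
#' @param adjust apply the regression adjustment (default `TRUE`).
#' @param seed master seed; spawns child seeds for every inner simulation.
#' @param chunk_size simulations per bridge batch (memory/latency
#'   trade-off).
#' @param verbose print per-stage timing.
#' @return an object of class `"tsabc"`; see [summary.tsabc()].
#' @export
tsabc <- function(observed, prior, cfg, backend = "true-ts", eta = 2500,
                  retain_frac = 1 / 20, mask = NULL, threshold = 0,
                  pairs = NULL, adjust = TRUE, seed,
                  chunk_size = 250, verbose = FALSE) {
  stopifnot(inherits(prior, "tsabc_prior"), inherits(cfg, "sim_config"),
            eta >= 20)
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(pairs)) pairs <- if (threshold > 0) "all" else "efficient"
  if (is.null(mask)) mask <- default_mask(prior)
  backend_name <- if (is.character(backend)) backend else "custom"
  if (identical(backend, "window-upgma")) backend <- infer_treeseq
  if (!identical(backend, "true-ts") && !is.function(backend)) {
    stop("backend must be \"true-ts\", \"window-upgma\" or a function")
  }
  if (!is.list(observed) || inherits(observed, c("tree_seq",
                                                 "haplotype_matrix"))) {
    observed <- list(observed)
  }
  if (length(observed) != cfg$chromosomes) {
    stop("observed has ", length(observed), " chromosome(s) but cfg says ",
         cfg$chromosomes)
  }
  if (identical(backend, "true-ts") && !inherits(observed[[1]], "tree_seq")) {
    stop("backend \"true-ts\" needs tree_seq observed data")
  }
  if (is.function(backend) && inherits(observed[[1]], "tree_seq")) {
    observed <- lapply(observed, to_haplotypes)
  }

  set.seed(seed)
  theta <- draw_prior(prior, eta)
  n_chrom <- cfg$chromosomes
  sim_seeds <- matrix(sample.int(2^31 - 2, eta * n_chrom), nrow = eta)
  err_seeds <- matrix(sample.int(2^31 - 2, eta * n_chrom), nrow = eta)

  t0 <- proc.time()[3]
  s_obs <- dataset_stats(observed, backend, pairs, threshold, mask)
  if (verbose) {
    message(sprintf("observed stats [%.1fs]: %s", proc.time()[3] - t0,
                    paste(names(s_obs), round(unclass(s_obs), 2),
                          sep = "=", collapse = " ")))
  }

  stats_ref <- matrix(NA_real_, eta, length(mask),
                      dimnames = list(NULL, mask))
  done <- 0L
  while (done < eta) {
    idx <- (done + 1L):min(done + chunk_size, eta)
    cfgs <- vector("list", length(idx) * n_chrom)
    pos <- 1L
    for (i in idx) {
      cfg_i <- apply_theta(cfg, theta[i, ])
      for (k in seq_len(n_chrom)) {
        ck <- cfg_i
        ck$chromosomes <- 1L
        ck$seed <- sim_seeds[i, k]
        cfgs[[pos]] <- ck
        pos <- pos + 1L
      }
    }
    ts_all <- simulate_batch(cfgs)
    pos <- 1L
    for (i in idx) {
      ds <- vector("list", n_chrom)
      eps_i <- if ("eps" %in% colnames(theta)) theta[i, "eps"] else cfg$eps
      for (k in seq_len(n_chrom)) {
        ts_k <- ts_all[[pos]]
        pos <- pos + 1L
        if (identical(backend, "true-ts")) {
          ds[[k]] <- simulate_error_on_ts(ts_k, eps_i,
                                          seed = err_seeds[i, k])
        } else {
          ds[[k]] <- inject_errors(to_haplotypes(ts_k), eps_i,
                                   seed = err_seeds[i, k])
        }
      }
      stats_ref[i, ] <- dataset_stats(ds, backend, pairs, threshold, mask)
    }
    done <- idx[length(idx)]
    if (verbose) {
      message(sprintf("simulated %d/%d [%.1fs]", done, eta,
                      proc.time()[3] - t0))
    }
  }

  scales <- apply(stats_ref, 2, stats::mad)
  use <- scales > 0
  if (!any(use)) {
    warning("all statistic scales are zero; using unscaled distance")
    scales[] <- 1
    use[] <- TRUE
  } else if (!all(use)) {
    warning("dropping degenerate statistic component(s): ",
            paste(mask[!use], collapse = ", "))
  }
  Zs <- sweep(sweep(stats_ref[, use, drop = FALSE], 2, s_obs[use], "-"),
              2, scales[use], "/")
  d <- sqrt(rowSums(Zs^2))

  k_keep <- round(eta * retain_frac)
  ord <- order(d, seq_along(d))      # ties broken by simulation index
  acc <- sort(ord[seq_len(k_keep)])
  adjusted <- theta[acc, , drop = FALSE]
  if (adjust && k_keep > sum(use) + 1) {
    adjusted <- linear_adjust(theta[acc, , drop = FALSE],
                              stats_ref[acc, use, drop = FALSE],
                              s_obs[use], d = d[acc],
                              scale = scales[use])
    adjusted <- clip_to_prior(adjusted, prior)
  }
  post_mean <- colMeans(adjusted)
  qs <- apply(adjusted, 2, stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975))

  structure(list(
    posterior_mean = post_mean, posterior_quantiles = qs,
    adjusted = adjusted, accepted = acc,
    draws = data.frame(theta, stats_ref, d = d, check.names = FALSE),
    s_obs = s_obs, scales = scales, mask = mask, used = use,
    eta = eta, retain_frac = retain_frac, threshold = threshold,
    pairs = if (is.character(pairs)) pairs else "custom",
    backend = backend_name, adjusted_flag = adjust, seed = seed,
    prior = prior, cfg = cfg,
    elapsed = proc.time()[3] - t0
  ), class = "tsabc")
}

#' @export
print.tsabc <- function(x, ...) {
  cat("TSABC fit (", x$backend, " backend, eta = ", x$eta, ", retained ",
      length(x$accepted), ", threshold ", x$threshold, ")\n", sep = "")
  cat("Posterior means:\n")
  print(x$posterior_mean)
  invisible(x)
}

#' @export
coef.tsabc <- function(object, ...) object$posterior_mean

#' Summary of a TSABC fit
#'
#' @param object a [tsabc()] result.
#' @param ... unused.
#' @return the object, invisibly, after printing posterior means,
#'   quantiles of the adjusted retained draws, observed statistics and
#'   run settings.
#' @export
summary.tsabc <- function(object, ...) {
  print(object)
  cat("\nPosterior quantiles (adjusted retained draws):\n")
  print(object$posterior_quantiles)
  cat("\nObserved statistics:\n")
  print(unclass(object$s_obs))
  cat(sprintf("\nStatistic scales (MAD over reference table): %s\n",
              paste(round(object$scales, 3), collapse = ", ")))
  cat(sprintf("Elapsed: %.1f s\n", object$elapsed))
  invisible(object)
}

#' @export
plot.tsabc <- function(x, ...) {
  p <- ncol(x$adjusted)
  old <- graphics::par(mfrow = c(1, p))
  on.exit(graphics::par(old))
  for (j in seq_len(p)) {
    nm <- colnames(x$adjusted)[j]
    graphics::hist(x$adjusted[, j], breaks = 20, main = nm, xlab = nm,
                   col = "grey85", border = "white", ...)
    graphics::abline(v = x$posterior_mean[j], col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Windowed-clustering tree-sequence inference (stand-in backend)
#'
#' Infers a rank-ordered tree sequence from binary haplotypes by cutting
#' the genome into fixed windows and building an average-linkage
#' clustering tree per window from pairwise Hamming distances.  This is a
#' deliberately simple stand-in for sequential tree-sequence inference
#' tools: crude, but deterministic and applied identically to observed
#' and simulated data, which is what the ABC machinery requires of a
#' backend.  Internal node ids are numbered in merge order within each
#' window and consecutively across windows, so `parent id > child id`
#' holds; node times are not assigned (rank order only).
#'
#' Adjacent windows whose inferred topology (the merge structure) is
#' identical share internal node ids, so the IBD partition of the
#' inferred sequence breaks only where the inferred tree changes — this
#' is what makes the IBD length statistics of the backend informative
#' rather than constant at the window width.
#'
#' @param h a [haplotype_matrix()].
#' @param window window width in sites (default 5e4).
#' @return a `tree_seq` without node times.
#' @export
infer_treeseq <- function(h, window = 5e4) {
  m <- h$m
  seq_len_ <- h$seq_len
  starts <- seq(1L, seq_len_, by = as.integer(window))
  ends <- c(starts[-1] - 1L, seq_len_)
  blocks <- vector("list", length(starts))
  nb <- 0L
  offset <- m
  prev_merge <- NULL
  cur <- NULL
  for (wi in seq_along(starts)) {
    in_w <- h$positions >= starts[wi] & h$positions <= ends[wi]
    dm <- if (any(in_w)) {
      stats::dist(h$mat[, in_w, drop = FALSE], method = "manhattan")
    } else {
      stats::dist(matrix(0, m, 1))
    }
    hc <- stats::hclust(dm, method = "average")
    if (!is.null(cur) && identical(hc$merge, prev_merge)) {
      cur$right <- ends[wi]  # same topology: extend the current tree
      next
    }
    if (!is.null(cur)) {
      nb <- nb + 1L
      blocks[[nb]] <- cur
    }
    node_of <- function(v) ifelse(v < 0, -v, offset + v)
    cur <- data.frame(
      child = c(node_of(hc$merge[, 1]), node_of(hc$merge[, 2])),
      parent = rep(offset + seq_len(m - 1L), 2),  # merge row k -> node
      left = starts[wi], right = ends[wi])
    offset <- offset + (m - 1L)
    prev_merge <- hc$merge
  }
  nb <- nb + 1L
  blocks[[nb]] <- cur
  tree_seq(m, seq_len_, do.call(rbind, blocks[seq_len(nb)]),
           validate = FALSE)
}
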