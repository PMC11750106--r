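#' Demographic models
#'
#' Haploid population size `N(g)` for `g >= 0` generations before the
#' present.  Four forms are supported:
#' \describe{
#'   \item{constant}{`N(g) = N`.}
#'   \item{exponential}{`N(g) = N0 * exp(-tau * g)`; for negative growth
#'     rate `tau` the size is capped at `2 * N0` going into the past.}
#'   \item{step}{`N(g) = N0` for `g < g_star`, `N_star` after.}
#'   \item{piecewise}{a table of `(g, N)` epochs, `g` ascending from 0.}
#' }
#'
#' @param kind one of `"constant"`, `"exponential"`, `"step"`,
#'   `"piecewise"`.
#' @param ... parameters for the chosen kind: `N`; `N0`, `tau`; `N0`,
#'   `g_star`, `N_star`; or `table` (data frame with columns `g`, `N`).
#' @return an object of class `"demographic_model"`.
#' @export
demographic_model <- function(kind = c("constant", "exponential", "step",
                                       "piecewise"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  mod <- switch(kind,
    constant = {
      stopifnot(p$N > 0)
      list(kind = "constant", N = p$N)
    },
    exponential = {
      stopifnot(p$N0 > 0)
      list(kind = "exponential", N0 = p$N0, tau = p$tau)
    },
    step = {
      stopifnot(p$N0 > 0, p$N_star > 0, p$g_star > 0)
      list(kind = "step", N0 = p$N0, g_star = p$g_star, N_star = p$N_star)
    },
    piecewise = {
      tab <- as.data.frame(p$table)
      stopifnot(all(c("g", "N") %in% names(tab)), all(tab$N > 0),
                tab$g[1] == 0, !is.unsorted(tab$g, strictly = TRUE))
      list(kind = "piecewise", g = tab$g, N = tab$N)
    })
  structure(mod, class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model:", x$kind, "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Population size at generation g
#'
#' @param model a [demographic_model()].
#' @param g generations before present (vectorised).
#' @return `N(g)`.
#' @export
popsize_at <- function(model, g) {
  switch(model$kind,
    constant = rep(model$N, length(g)),
    exponential = {
      n <- model$N0 * exp(-model$tau * g)
      if (model$tau < 0) n <- pmin(n, 2 * model$N0)
      n
    },
    step = ifelse(g < model$g_star, model$N0, model$N_star),
    piecewise = model$N[findInterval(g, model$g)]
  )
}

#' Standard study models
#'
#' Convenience constructors for the demographic models of the simulation
#' study: constant size (`model_c`), exponential decline into the past in
#' two parameterisations (`model_ga`, `model_gb`), a two-epoch step
#' (`model_s`), and a synthetic piecewise European-American-like history
#' (`model_ea_synthetic`; a synthetic stand-in table shipped with the
#' package, not an estimate of any real population's history).
#'
#' @return a [demographic_model()].
#' @export
model_c <- function() demographic_model("constant", N = 2e4)

#' @rdname model_c
#' @export
model_ga <- function() demographic_model("exponential", N0 = 1e6,
                                         tau = 1e-4)

#' @rdname model_c
#' @export
model_gb <- function() demographic_model("exponential", N0 = 2e5,
                                         tau = 1e-3)

#' @rdname model_c
#' @export
model_s <- function() demographic_model("step", N0 = 4e4, g_star = 4e4,
                                        N_star = 1e4)

#' @rdname model_c
#' @export
model_ea_synthetic <- function() {
  path <- system.file("extdata", "model_ea_synthetic.tsv",
                      package = "tsabc")
  demographic_model("piecewise",
                    table = utils::read.table(path, header = TRUE))
}

#' Simulation configuration
#'
#' Bundles everything the coalescent-with-recombination generator needs.
#'
#' @param m sample size (haploid sequences).
#' @param seq_len genome length in sites.
#' @param mu mutation rate per site per generation.
#' @param eps sequencing error rate per site (applied downstream by
#'   [simulate_error_on_ts()] or [inject_errors()]; not part of the
#'   coalescent itself).
#' @param recomb constant recombination rate per site per generation, or a
#'   genetic map from [read_genetic_map()].
#' @param model a [demographic_model()].
#' @param gene_conversion `NULL`, or `list(rate =, tract_length =)`;
#'   a data-generation challenge only, never part of the inference model.
#' @param chromosomes number of independent chromosomes (each simulated as
#'   its own tree sequence with the same parameters).
#' @param seed integer seed; mandatory for reproducibility.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(m, seq_len, mu = 1.3e-8, eps = 0, recomb = 1e-8,
                       model = model_c(), gene_conversion = NULL,
                       chromosomes = 1, seed) {
  stopifnot(m >= 2, seq_len >= 2, mu >= 0, eps >= 0, chromosomes >= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (!is.null(gene_conversion)) {
    stopifnot(gene_conversion$rate >= 0, gene_conversion$tract_length > 0)
  }
  structure(list(m = as.integer(m), seq_len = as.integer(seq_len), mu = mu,
                 eps = eps, recomb = recomb, model = model,
                 gene_conversion = gene_conversion,
                 chromosomes = as.integer(chromosomes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

cfg_to_job <- function(cfg, seed) {
  sim <- list(m = cfg$m, seq_len = cfg$seq_len, mu = cfg$mu,
              seed = seed, model = unclass(cfg$model))
  if (inherits(cfg$recomb, "genetic_map")) {
    sim$map_pos <- cfg$recomb$pos
    sim$map_rate <- cfg$recomb$rate
  } else {
    sim$recomb_rate <- cfg$recomb
  }
  if (!is.null(cfg$gene_conversion)) {
    sim$gene_conversion <- list(rate = cfg$gene_conversion$rate,
                                tract_length =
                                  cfg$gene_conversion$tract_length)
  }
  sim
}

#' Batched coalescent simulation
#'
#' Simulates many tree sequences in one Python/msprime process (interpreter
#' start-up is amortised over the batch).  Deterministic given the seeds in
#' the configurations.
#'
#' @param cfgs list of [sim_config()]s (each with `chromosomes = 1`; use
#'   [simulate_treeseq()] for multi-chromosome genomes).
#' @return list of `tree_seq` objects, one per configuration.
#' @export
simulate_batch <- function(cfgs) {
  stopifnot(length(cfgs) >= 1)
  prefix <- tempfile("simbatch")
  job <- list(out_prefix = prefix,
              sims = lapply(cfgs, function(cfg) {
                cfg_to_job(cfg, cfg$seed)
              }))
  jobfile <- paste0(prefix, ".json")
  jsonlite::write_json(job, jobfile, auto_unbox = TRUE, digits = NA)
  on.exit(unlink(paste0(prefix, c(".json", ".nodes.tsv", ".edges.tsv",
                                  ".muts.tsv", ".done"))))
  run_py(py_script("sim_batch.py"), jobfile)
  if (!file.exists(paste0(prefix, ".done"))) {
    stop("simulation bridge did not complete")
  }
  nodes <- data.table::fread(paste0(prefix, ".nodes.tsv"),
                             data.table = FALSE)
  edges <- data.table::fread(paste0(prefix, ".edges.tsv"),
                             data.table = FALSE)
  muts <- data.table::fread(paste0(prefix, ".muts.tsv"),
                            data.table = FALSE)
  n_sets <- length(cfgs)
  nodes_by <- split_by_dataset(nodes, n_sets)
  edges_by <- split_by_dataset(edges, n_sets)
  muts_by <- split_by_dataset(muts, n_sets)
  lapply(seq_len(n_sets), function(i) {
    nd <- nodes_by[[i]]
    tree_seq(m = cfgs[[i]]$m, seq_len = cfgs[[i]]$seq_len,
             edges = edges_by[[i]], mutations = muts_by[[i]],
             node_times = nd$time[order(nd$id)], validate = FALSE)
  })
}

split_by_dataset <- function(df, n_sets) {
  out <- split(df[setdiff(names(df), "dataset")],
               factor(df$dataset, levels = seq_len(n_sets)))
  lapply(out, function(x) { rownames(x) <- NULL; x })
}

#' Simulate a tree sequence under the coalescent with recombination
#'
#' Runs the coalescent-with-recombination generator (msprime, through the
#' bundled bridge) under the configured demographic model, then places
#' mutations on branches at rate `mu` per site per generation (binary,
#' possibly recurrent).  Node times are in generations.  Deterministic
#' given `cfg$seed`.
#'
#' Sequencing error is not added here; see [simulate_error_on_ts()] (error
#' records on the tree sequence, for true-IBD studies) and
#' [inject_errors()] (on haplotypes, for inferred-IBD studies).
#'
#' @param cfg a [sim_config()].
#' @return a `tree_seq` with node times, or a list of `cfg$chromosomes`
#'   of them.
#' @export
simulate_treeseq <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$chromosomes == 1) {
    return(simulate_batch(list(cfg))[[1]])
  }
  cfgs <- lapply(seq_len(cfg$chromosomes), function(k) {
    ck <- cfg
    ck$chromosomes <- 1L
    ck$seed <- cfg$seed + (k - 1L) * 1000003L
    ck
  })
  simulate_batch(cfgs)
}

#' Add sequencing-error records to a tree sequence
#'
#' Simulates the basic error model by adding mismatch records at leaf
#' nodes: each (leaf, site) entry independently gains a record with
#' probability `eps`.  Used for true-IBD experiments, where errors live in
#' the mismatch table `M` rather than in exported haplotypes.
#'
#' @param ts a `tree_seq`.
#' @param eps per-site error rate in `[0, 0.01]`.
#' @param seed optional integer seed (local RNG stream).
#' @return a `tree_seq` with augmented mismatch records.
#' @export
simulate_error_on_ts <- function(ts, eps, seed = NULL) {
  stopifnot(eps >= 0, eps <= 1e-2)
  if (eps == 0) return(ts)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  k <- stats::rbinom(1, as.numeric(ts$m) * ts$seq_len, eps)
  if (k == 0) return(ts)
  cells <- sample_cells(k, ts$m, ts$seq_len)
  extra <- data.frame(node = cells$row, site = cells$site)
  tree_seq(ts$m, ts$seq_len, ts$edges,
           rbind(ts$mutations, extra), ts$node_times, validate = FALSE)
}

#' Read a HapMap-style genetic map
#'
#' Plain-text table with columns position (bp), recombination rate
#' (cM/Mb) and cumulative map distance (cM); a header line is detected and
#' skipped.  The per-site per-generation rate used by the simulator is
#' `cM/Mb * 1e-8`.
#'
#' @param path map file.
#' @return an object of class `"genetic_map"`: list with `pos` (0-based
#'   interval starts for the simulator) and `rate` (per site per
#'   generation).
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, 1)
  has_header <- !grepl("^[0-9]", trimws(strsplit(first, "[ \t]+")[[1]][1]))
  tab <- utils::read.table(path, header = has_header)
  if (ncol(tab) < 3) stop("expected >= 3 columns: position, cM/Mb, cM")
  names(tab)[1:3] <- c("pos", "rate_cm_mb", "cm")
  stopifnot(!is.unsorted(tab$pos, strictly = TRUE), all(tab$rate_cm_mb >= 0))
  structure(list(pos = tab$pos, rate = tab$rate_cm_mb * 1e-8,
                 table = tab),
            class = "genetic_map")
}
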