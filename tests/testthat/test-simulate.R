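test_that("demographic models evaluate N(g) as specified", {
  expect_equal(popsize_at(model_c(), c(0, 1e5)), c(2e4, 2e4))
  # exponential decline into the past, Model Ga parameterisation
  expect_equal(popsize_at(model_ga(), c(0, 1e4)),
               1e6 * exp(-1e-4 * c(0, 1e4)))
  # negative tau grows into the past and is capped at 2 N(0)
  g <- demographic_model("exponential", N0 = 1e4, tau = -1e-4)
  expect_equal(popsize_at(g, 0), 1e4)
  expect_equal(popsize_at(g, 1e6), 2e4)   # capped
  expect_equal(popsize_at(model_s(), c(3.9e4, 4e4)), c(4e4, 1e4))
  pw <- demographic_model("piecewise",
                          table = data.frame(g = c(0, 100), N = c(5, 9)))
  expect_equal(popsize_at(pw, c(0, 99, 100, 1e5)), c(5, 5, 9, 9))
  expect_error(demographic_model("constant", N = -5))
  ea <- model_ea_synthetic()
  expect_s3_class(ea, "demographic_model")
  expect_true(all(popsize_at(ea, c(0, 1e3, 1e5)) > 0))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(m = 4, seq_len = 1e4, mu = 1e-7, seed = 99)
  ts1 <- simulate_treeseq(cfg)
  ts2 <- simulate_treeseq(cfg)
  expect_identical(ts1$edges, ts2$edges)
  expect_identical(ts1$mutations, ts2$mutations)
  expect_identical(ts1$node_times, ts2$node_times)
  ts3 <- simulate_treeseq(sim_config(m = 4, seq_len = 1e4, mu = 1e-7,
                                     seed = 100))
  expect_false(identical(ts3$edges, ts1$edges))
})

test_that("pair TMRCA and diversity match coalescent expectations", {
  # mean pair TMRCA under constant N is N; average over replicates
  cfgs <- lapply(1:300, function(i) {
    sim_config(m = 2, seq_len = 100, mu = 0, recomb = 0, seed = 5000 + i)
  })
  tl <- simulate_batch(cfgs)
  tmrca <- vapply(tl, function(ts) max(ts$node_times), 0)
  se <- sd(tmrca) / sqrt(length(tmrca))
  expect_lt(abs(mean(tmrca) - 2e4), 4 * se)

  # mean pairwise diversity ~ 2 N mu per site
  cfg <- sim_config(m = 10, seq_len = 1e6, mu = 1.3e-8, seed = 314)
  ts <- simulate_treeseq(cfg)
  h <- to_haplotypes(ts)
  pr <- tsabc:::all_pairs(10)
  pi_hat <- mean(apply(pr, 1, function(p) {
    sum(h$mat[p[1], ] != h$mat[p[2], ])
  })) / 1e6
  expect_lt(abs(pi_hat - 5.2e-4) / 5.2e-4, 0.35)  # generous MC band

  # simulated tree sequences satisfy the structural invariants
  small <- simulate_treeseq(sim_config(m = 6, seq_len = 500, mu = 1e-6,
                                       recomb = 1e-5, seed = 8))
  expect_true(check_paths(small))
  expect_true(edge_coverage_check(small)$ok)
})

test_that("error injection on haplotypes flips cells at rate eps", {
  set.seed(21)
  h <- haplotype_matrix(matrix(0L, 10, 2), c(5L, 9L), 1e6L)
  h$mat[1, 1] <- 1L
  expect_identical(inject_errors(h, 0), h)
  h2 <- inject_errors(h, 1e-3, seed = 77)
  flips <- sum(h2$mat) - sum(h$mat)
  expected <- 10 * 1e6 * 1e-3
  expect_lt(abs(flips - expected), 4 * sqrt(expected))
  # original derived allele untouched
  expect_equal(h2$mat[1, h2$positions == 5L], 1L)
  # reproducible given the seed, and the caller RNG stream is unaffected
  expect_identical(inject_errors(h, 1e-3, seed = 77), h2)
})

test_that("error injection inflates the singleton count by ~ m l eps", {
  cfg <- sim_config(m = 10, seq_len = 1e6, mu = 1.3e-8, seed = 271)
  ts <- simulate_treeseq(cfg)
  h <- to_haplotypes(ts)
  c1_before <- sum(colSums(h$mat) == 1)
  h2 <- inject_errors(h, 1e-3, seed = 3)
  c1_after <- sum(colSums(h2$mat) == 1)
  excess <- c1_after - c1_before
  expected <- 10 * 1e6 * 1e-3
  expect_lt(abs(excess - expected) / expected, 0.05)
})

test_that("error records on the tree sequence sit on leaves only", {
  cfg <- sim_config(m = 8, seq_len = 1e5, mu = 1.3e-8, seed = 41)
  ts <- simulate_treeseq(cfg)
  expect_identical(simulate_error_on_ts(ts, 0), ts)
  ts2 <- simulate_error_on_ts(ts, 1e-3, seed = 9)
  expect_gt(nrow(ts2$mutations), nrow(ts$mutations))
  extra <- setdiff(
    paste(ts2$mutations$node, ts2$mutations$site),
    paste(ts$mutations$node, ts$mutations$site))
  nodes <- as.integer(sub(" .*", "", extra))
  expect_true(all(nodes >= 1 & nodes <= 8))

  # pairwise mismatch totals rise by ~ 2 eps L per segment
  h1 <- to_haplotypes(ts); h2 <- to_haplotypes(ts2)
  mm <- function(h) sum(h$mat[1, ] != h$mat[2, ])
  rise <- mm(h2) - mm(h1)
  expected <- 2 * 1e-3 * 1e5
  expect_lt(abs(rise - expected), 5 * sqrt(expected))
})

test_that("multi-chromosome genomes come back as independent replicates", {
  cfg <- sim_config(m = 4, seq_len = 1e4, mu = 1e-7, chromosomes = 3,
                    seed = 1234)
  tl <- simulate_treeseq(cfg)
  expect_length(tl, 3)
  expect_false(identical(tl[[1]]$edges, tl[[2]]$edges))
})

test_that("a genetic map and gene conversion are accepted by the bridge", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("pos rate cm", "1 1.0 0", "50000 5.0 0.05",
               "100000 1.0 0.3"), path)
  gm <- read_genetic_map(path)
  cfg <- sim_config(m = 4, seq_len = 1e5, mu = 1e-7, recomb = gm,
                    seed = 5150)
  ts <- simulate_treeseq(cfg)
  expect_s3_class(ts, "tree_seq")
  expect_gt(nrow(ts$edges), 0)
  cfg2 <- sim_config(m = 4, seq_len = 1e5, mu = 1e-7,
                     gene_conversion = list(rate = 2e-8,
                                            tract_length = 300),
                     seed = 5151)
  expect_s3_class(simulate_treeseq(cfg2), "tree_seq")
})
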