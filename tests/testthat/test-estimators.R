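# deterministic three-leaf caterpillar: node 4 = MRCA(1,2) at g1,
# node 5 = root at g2, one tree over L sites
caterpillar3 <- function(L = 1e5, g1 = 5e3, g2 = 2e4) {
  ed <- data.frame(child = c(1L, 2L, 4L, 3L), parent = c(4L, 4L, 5L, 5L),
                   left = 1L, right = as.integer(L))
  list(L = L, g1 = g1, g2 = g2, ed = ed, times = c(0, 0, 0, g1, g2))
}

test_that("moment equations invert their own generative model exactly", {
  cat3 <- caterpillar3()
  # mutations placed deterministically at rate mu per site-generation:
  # branch above leaf 1 and 2: mu*g1*L = 5 each; leaf 3: mu*g2*L = 20;
  # internal branch 4->5: mu*(g2-g1)*L = 15  (mu = 1e-8)
  mu_true <- 1e-8
  muts <- data.frame(
    node = rep(c(1L, 2L, 3L, 4L), c(5, 5, 20, 15)),
    site = 1:45)
  ts <- tree_seq(3, cat3$L, cat3$ed, mutations = muts,
                 node_times = cat3$times)
  seg <- extract_ibd(ts, pairs = "all")
  fit <- mm_estimate(seg, ts, order = "first")
  expect_equal(fit$mu, mu_true, tolerance = 1e-10)
  expect_equal(fit$eps, 0, tolerance = 1e-12)

  # add deterministic "errors": eps*L = 10 records per leaf
  eps_true <- 1e-4
  err <- data.frame(node = rep(1:3, each = 10), site = 101:130)
  ts2 <- tree_seq(3, cat3$L, cat3$ed, mutations = rbind(muts, err),
                  node_times = cat3$times)
  seg2 <- extract_ibd(ts2, pairs = "all")
  fit2 <- mm_estimate(seg2, ts2, order = "first")
  expect_equal(fit2$mu, mu_true, tolerance = 1e-10)
  expect_equal(fit2$eps, eps_true, tolerance = 1e-8)
  expect_equal(coef(fit2), c(mu = fit2$mu, eps = fit2$eps))
  # the default second-order system agrees to within its correction size
  fit3 <- mm_estimate(seg2, ts2)
  expect_equal(fit3$mu, mu_true, tolerance = 2e-3)
  expect_equal(fit3$eps, eps_true, tolerance = 2e-3)
})

test_that("moment system failure modes are reported", {
  cat3 <- caterpillar3()
  ts <- tree_seq(3, cat3$L, cat3$ed,
                 mutations = data.frame(node = 1L, site = 1L),
                 node_times = c(0, 0, 0, 0, 0))  # all TMRCAs zero
  seg <- extract_ibd(ts, pairs = "all")
  expect_error(mm_estimate(seg, ts), "singular")
  ts2 <- tree_seq(3, cat3$L, cat3$ed)  # no times at all
  expect_error(mm_estimate(extract_ibd(ts2), ts2), "TMRCA")
})

test_that("per-segment TMRCA estimate follows the stated inversion", {
  seg <- data.frame(l = 1, r = 1e5, n_mismatch = 26)
  expect_equal(estimate_tmrca(seg, mu = 1.3e-8), 1e4)
  # mismatch-free segments hit the floor
  seg0 <- data.frame(l = 1, r = 50, n_mismatch = 0)
  expect_equal(estimate_tmrca(seg0, mu = 1.3e-8), 1)
  expect_equal(estimate_tmrca(seg0, mu = 1.3e-8, g_floor = 5), 5)
  # error correction subtracts 2*eps from the mismatch fraction
  expect_equal(estimate_tmrca(seg, mu = 1.3e-8, eps = 5e-5),
               (26 / 1e5 - 1e-4) / (2 * 1.3e-8))
  # monotone in the mismatch count, antitone in L
  set.seed(1)
  base <- data.frame(l = 1, r = 1e4, n_mismatch = 10)
  g_up <- estimate_tmrca(transform(base, n_mismatch = 11), mu = 1e-8)
  g_wide <- estimate_tmrca(transform(base, r = 2e4), mu = 1e-8)
  g0 <- estimate_tmrca(base, mu = 1e-8)
  expect_gt(g_up, g0)
  expect_lt(g_wide, g0)
})

test_that("hazard-based N(g) is flat for exponential TMRCAs", {
  set.seed(2024)
  g <- rexp(2e4, rate = 1 / 2e4)
  cur <- estimate_popsize(g)
  expect_true(isTRUE(attr(cur, "reliable")))
  # central 90% of the mass
  qs <- quantile(g, c(0.05, 0.95))
  mid <- cur$g >= qs[1] & cur$g <= qs[2]
  expect_true(all(abs(cur$N[mid] / 2e4 - 1) < 0.10))
})

test_that("two-epoch N(g) is recovered within kernel blur", {
  # step model: N0 = 4e4 up to g* = 4e4, then N* = 1e4; sample pair
  # TMRCAs by inverting the survival function
  set.seed(55)
  n0 <- 4e4; gs <- 4e4; ns <- 1e4
  u <- runif(3e4)
  e <- -log(u)
  g <- ifelse(e <= gs / n0, n0 * e, gs + ns * (e - gs / n0))
  cur <- estimate_popsize(g)
  early <- cur$g >= 3e3 & cur$g <= 1.5e4   # well inside epoch 1
  late <- cur$g >= 6e4 & cur$g <= 7.5e4    # well past the step
  expect_true(all(abs(cur$N[early] / n0 - 1) < 0.15))
  expect_true(all(abs(cur$N[late] / ns - 1) < 0.25))
})

test_that("degenerate TMRCA samples are flagged unreliable", {
  expect_warning(cur <- estimate_popsize(rep(100, 200)), "degenerate")
  expect_false(attr(cur, "reliable"))
  expect_true(all(is.na(cur$N)))
  expect_error(estimate_popsize(numeric(0)), "no")
  expect_warning(estimate_popsize(rexp(50, 1 / 100)), "fewer than 100")
})

test_that("popsize TSV export round-trips the grid", {
  set.seed(3)
  cur <- estimate_popsize(rexp(500, 1 / 1e3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_popsize(cur, path)
  back <- read.delim(path)
  expect_equal(back$g, cur$g)
  expect_equal(back$N, cur$N)
})
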