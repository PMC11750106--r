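# Independent brute-force oracles and a pure-R random tree-sequence
# generator.  The oracles deliberately share no code with the package's
# sweep implementation: they rebuild the marginal tree at every site.

# parent map (named integer vector over 1..n_nodes) at one site
parent_map_at <- function(ts, s) {
  act <- ts$edges$left <= s & ts$edges$right >= s
  par <- integer(ts$n_nodes)
  par[ts$edges$child[act]] <- ts$edges$parent[act]
  par
}

site_mrca_oracle <- function(ts, a, b, s) {
  par <- parent_map_at(ts, s)
  anc <- a
  u <- a
  while (par[u] != 0L) { u <- par[u]; anc <- c(anc, u) }
  v <- b
  while (!(v %in% anc)) {
    if (par[v] == 0L) return(0L)
    v <- par[v]
  }
  v
}

# run-length merge of the per-site MRCA into segments
partition_oracle <- function(ts, pair) {
  mr <- vapply(seq_len(ts$seq_len), function(s) {
    site_mrca_oracle(ts, pair[1], pair[2], s)
  }, integer(1))
  rl <- rle(mr)
  ends <- cumsum(rl$lengths)
  data.frame(c1 = min(pair), c2 = max(pair),
             l = c(1L, head(ends, -1) + 1L), r = ends, mrca = rl$values)
}

# genotype of each leaf at each mutated site by explicit path traversal
haplotype_oracle <- function(ts) {
  sites <- sort(unique(ts$mutations$site))
  G <- matrix(0L, ts$m, length(sites))
  for (j in seq_along(sites)) {
    s <- sites[j]
    par <- parent_map_at(ts, s)
    hit <- table(ts$mutations$node[ts$mutations$site == s])
    for (leaf in seq_len(ts$m)) {
      u <- leaf
      parity <- 0L
      repeat {
        parity <- (parity + sum(hit[as.character(u)], na.rm = TRUE)) %% 2L
        if (par[u] == 0L) break
        u <- par[u]
      }
      G[leaf, j] <- parity
    }
  }
  list(pos = sites, G = G)
}

# random topology as a parent vector; internal ids assigned in merge order
random_topology <- function(m, first_id) {
  active <- seq_len(m)
  par <- integer(0)
  nid <- first_id
  while (length(active) > 1) {
    pick <- sample(length(active), 2)
    nid <- nid + 1L
    par[active[pick]] <- nid
    active <- c(active[-pick], nid)
  }
  par  # indexed by node id, 0/NA for root and untouched ids
}

# Random multi-tree tree sequence.  Each new interval either regrafts one
# leaf under a fresh root (recombination changing only some pairs' MRCAs)
# or draws a completely fresh topology (ids keep increasing either way, so
# parent id > child id always holds).
random_treeseq <- function(m = NULL, seq_len = NULL, n_breaks = NULL,
                           mutations = TRUE) {
  if (is.null(m)) m <- sample(2:10, 1)
  if (is.null(seq_len)) seq_len <- sample(20:500, 1)
  if (is.null(n_breaks)) n_breaks <- sample(0:4, 1)
  n_breaks <- min(n_breaks, seq_len - 1)
  bp <- sort(sample(2:seq_len, n_breaks))
  starts <- c(1L, bp)
  ends <- c(bp - 1L, seq_len)
  par <- random_topology(m, m)
  max_id <- max(m, which(par > 0), par, na.rm = TRUE)
  edges <- NULL
  for (k in seq_along(starts)) {
    if (k > 1) {
      if (stats::runif(1) < 0.5) {
        par <- random_topology(m, max_id)
      } else {
        x <- sample(m, 1)
        root <- x
        while (!is.na(par[root]) && par[root] != 0L &&
               length(par) >= root && par[root] > 0) root <- par[root]
        q <- max_id + 1L
        par[x] <- q
        if (root != x) par[root] <- q
      }
      max_id <- max(max_id, which(par > 0), par, na.rm = TRUE)
    }
    ch <- which(!is.na(par) & par > 0)
    edges <- rbind(edges, data.frame(child = ch, parent = par[ch],
                                     left = starts[k], right = ends[k]))
  }
  # merge adjacent intervals of identical (child, parent)
  edges <- edges[order(edges$child, edges$parent, edges$left), ]
  merged <- NULL
  for (i in seq_len(nrow(edges))) {
    if (!is.null(merged) &&
        merged$child[nrow(merged)] == edges$child[i] &&
        merged$parent[nrow(merged)] == edges$parent[i] &&
        merged$right[nrow(merged)] + 1L == edges$left[i]) {
      merged$right[nrow(merged)] <- edges$right[i]
    } else {
      merged <- rbind(merged, edges[i, ])
    }
  }
  muts <- NULL
  if (mutations) {
    k <- stats::rpois(1, seq_len / 20)
    if (k > 0) {
      sites <- sample(seq_len, k, replace = TRUE)
      nodes <- vapply(sites, function(s) {
        cand <- merged$child[merged$left <= s & merged$right >= s]
        cand[sample(length(cand), 1)]
      }, integer(1))
      muts <- data.frame(node = nodes, site = sites)
    }
  }
  n_all <- max(merged$parent)
  tree_seq(m, seq_len, merged, mutations = muts,
           node_times = rep(NA_real_, n_all))
}
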