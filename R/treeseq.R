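#' Construct a succinct tree sequence
#'
#' A succinct tree sequence encodes the genealogical history of `m` sampled
#' haploid sequences along a genome of `seq_len` sites as a set of
#' inheritance edges over genome intervals, plus per-node mismatch records
#' (mutations, or sequencing errors at leaf nodes).  Leaf nodes are
#' `1..m`; internal (ancestral) nodes are `m+1..n`, ordered backwards in
#' time from the present so that on every leaf-to-root path node ids
#' strictly increase.  All coordinates are 1-based closed intervals
#' `[l, r]` with `1 <= l <= r <= seq_len`.
#'
#' @param m number of leaf (sample) nodes.
#' @param seq_len genome length in sites.
#' @param edges data frame with integer columns `child`, `parent`, `left`,
#'   `right`: inheritance of sites `[left, right]` from `parent` to `child`.
#' @param mutations data frame with integer columns `node`, `site`, or
#'   `NULL` for none.  A leaf carries the derived state at a site iff an
#'   odd number of records lie on its path to the root at that site.
#' @param node_times optional numeric vector of node ages in generations,
#'   indexed by node id (length `n`).  `NA` throughout means only the rank
#'   order of coalescences is known (as for an inferred tree sequence);
#'   leaves have time 0.
#' @param validate check invariants (see [validate_treeseq()]).
#' @return an object of class `"tree_seq"`.
#' @seealso [load_treeseq()], [write_treeseq()], [fixture_fig2()]
#' @export
tree_seq <- function(m, seq_len, edges, mutations = NULL, node_times = NULL,
                     validate = TRUE) {
  stopifnot(m >= 1, seq_len >= 1)
  edges <- as.data.frame(edges)
  stopifnot(all(c("child", "parent", "left", "right") %in% names(edges)))
  edges <- data.frame(
    child = as.integer(edges$child), parent = as.integer(edges$parent),
    left = as.integer(edges$left), right = as.integer(edges$right)
  )
  if (is.null(mutations)) {
    mutations <- data.frame(node = integer(), site = integer())
  } else {
    mutations <- as.data.frame(mutations)
    mutations <- data.frame(node = as.integer(mutations$node),
                            site = as.integer(mutations$site))
    mutations <- mutations[order(mutations$site, mutations$node), ,
                           drop = FALSE]
    rownames(mutations) <- NULL
  }
  n <- max(m, edges$parent, edges$child, mutations$node)
  if (is.null(node_times)) node_times <- rep(NA_real_, n)
  stopifnot(length(node_times) >= n)
  ts <- structure(
    list(m = as.integer(m), seq_len = as.integer(seq_len),
         n_nodes = as.integer(n), edges = edges, mutations = mutations,
         node_times = as.numeric(node_times[1:n])),  # n >= m >= 1
    class = "tree_seq"
  )
  if (validate) validate_treeseq(ts)
  ts
}

#' Validate tree-sequence invariants
#'
#' Checks that every edge interval satisfies `1 <= left <= right <=
#' seq_len`, that `parent > child` for every edge (nodes are ordered
#' backwards in time), that leaf ids are `1..m`, that no child has two
#' parents over overlapping intervals, and that mismatch records point to
#' existing nodes and sites.  Errors name the offending edge or node.
#'
#' @param ts a `tree_seq`.
#' @return `ts`, invisibly.
#' @export
validate_treeseq <- function(ts) {
  e <- ts$edges
  bad <- which(e$left < 1L | e$right > ts$seq_len | e$left > e$right)
  if (length(bad)) {
    stop("edge ", bad[1], " violates 1 <= left <= right <= seq_len: (",
         paste(e[bad[1], ], collapse = ", "), ")")
  }
  bad <- which(e$parent <= e$child)
  if (length(bad)) {
    stop("edge ", bad[1], ": parent id (", e$parent[bad[1]],
         ") must exceed child id (", e$child[bad[1]],
         "); nodes are ordered backwards in time")
  }
  if (any(e$child < 1L) || any(e$parent > ts$n_nodes)) {
    stop("edge node ids out of range 1..", ts$n_nodes)
  }
  # one parent per child per site
  if (nrow(e) > 1) {
    o <- order(e$child, e$left)
    ov <- which(diff(e$child[o]) == 0 &
                  e$left[o][-1] <= e$right[o][-length(o)])
    if (length(ov)) {
      stop("child ", e$child[o][ov[1] + 1],
           " has two parents over overlapping intervals")
    }
  }
  mu <- ts$mutations
  if (nrow(mu)) {
    if (any(mu$node < 1L | mu$node > ts$n_nodes)) {
      stop("mismatch record node id out of range")
    }
    if (any(mu$site < 1L | mu$site > ts$seq_len)) {
      stop("mismatch record site out of range 1..", ts$seq_len)
    }
  }
  if (!all(is.na(ts$node_times))) {
    tt <- ts$node_times
    ok <- is.na(tt[e$parent]) | is.na(tt[e$child]) |
      tt[e$parent] >= tt[e$child]
    if (!all(ok)) stop("edge ", which(!ok)[1], ": parent older than child?")
  }
  invisible(ts)
}

#' @export
print.tree_seq <- function(x, ...) {
  cat("Succinct tree sequence\n")
  cat(sprintf("  leaves: %d   nodes: %d   sites: %d\n",
              x$m, x$n_nodes, x$seq_len))
  cat(sprintf("  edges: %d   mismatch records: %d   node times: %s\n",
              nrow(x$edges), nrow(x$mutations),
              if (all(is.na(x$node_times))) "rank order only" else "known"))
  invisible(x)
}

#' Check per-site path uniqueness on a small tree sequence
#'
#' Exhaustively verifies that at every site every leaf has a unique path of
#' edges to a single shared root.  Intended for fixtures and simulated
#' instances with `seq_len <= ~1000`; cost is O(seq_len * m * depth).
#'
#' @param ts a `tree_seq`.
#' @return `TRUE`, or an error describing the first failing site.
#' @export
check_paths <- function(ts) {
  for (s in seq_len(ts$seq_len)) {
    act <- ts$edges$left <= s & ts$edges$right >= s
    par <- integer(ts$n_nodes)
    ch <- ts$edges$child[act]
    if (anyDuplicated(ch)) stop("site ", s, ": child with two parents")
    par[ch] <- ts$edges$parent[act]
    roots <- integer(0)
    for (leaf in seq_len(ts$m)) {
      u <- leaf
      steps <- 0L
      while (par[u] != 0L) {
        u <- par[u]
        steps <- steps + 1L
        if (steps > ts$n_nodes) stop("site ", s, ": cycle detected")
      }
      roots <- union(roots, u)
    }
    if (length(roots) != 1L) {
      stop("site ", s, ": leaves reach ", length(roots), " roots")
    }
  }
  TRUE
}

ts_text_header <- "#treeseq-text 1"

#' Write a tree sequence to the plain-text table container
#'
#' The container stores the node, edge and mismatch tables as
#' tab-separated sections with the 1-based closed coordinates used
#' throughout the package.  [read_treeseq()] inverts it exactly.
#'
#' @param ts a `tree_seq`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_treeseq <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ts_text_header, con)
  writeLines(sprintf("m %d", ts$m), con)
  writeLines(sprintf("seq_len %d", ts$seq_len), con)
  writeLines("#nodes", con)
  writeLines("id\ttime", con)
  tt <- ifelse(is.na(ts$node_times), "NA",
               formatC(ts$node_times, digits = 10, format = "g"))
  writeLines(paste(seq_len(ts$n_nodes), tt, sep = "\t"), con)
  writeLines("#edges", con)
  writeLines("child\tparent\tleft\tright", con)
  e <- ts$edges
  if (nrow(e)) {
    writeLines(paste(e$child, e$parent, e$left, e$right, sep = "\t"), con)
  }
  writeLines("#mutations", con)
  writeLines("node\tsite", con)
  mu <- ts$mutations
  if (nrow(mu)) writeLines(paste(mu$node, mu$site, sep = "\t"), con)
  invisible(path)
}

#' Read a tree sequence from the plain-text table container
#'
#' @param path file written by [write_treeseq()] (or exported from the
#'   binary container by the bundled converter).
#' @param validate check invariants after reading.
#' @return a `tree_seq`.
#' @export
read_treeseq <- function(path, validate = TRUE) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != ts_text_header) {
    stop("not a treeseq-text file: ", path)
  }
  sec <- cumsum(lines %in% c("#nodes", "#edges", "#mutations"))
  meta <- lines[sec == 0][-1]
  kv <- strsplit(meta[nzchar(meta)], " ")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  read_sec <- function(k, what) {
    body <- lines[sec == k]
    body <- body[-c(1, 2)]  # section tag + header row
    body <- body[nzchar(body)]
    if (!length(body)) {
      return(as.data.frame(stats::setNames(
        rep(list(numeric(0)), length(what)), what)))
    }
    out <- utils::read.table(text = body, sep = "\t", col.names = what,
                             na.strings = "NA")
    out
  }
  nodes <- read_sec(1, c("id", "time"))
  edges <- read_sec(2, c("child", "parent", "left", "right"))
  muts <- read_sec(3, c("node", "site"))
  nt <- rep(NA_real_, max(nodes$id, 1))
  nt[nodes$id] <- nodes$time
  tree_seq(m = as.integer(meta[["m"]]),
           seq_len = as.integer(meta[["seq_len"]]),
           edges = edges, mutations = muts, node_times = nt,
           validate = validate)
}

#' Load a tree sequence from disk
#'
#' Accepts either the package's plain-text table container (see
#' [write_treeseq()]) or a binary `.trees` file in the standard succinct
#' tree-sequence container format; the latter is converted through the
#' bundled Python/tskit bridge, which must be available on the system.
#'
#' @param path path to a tree-sequence file.
#' @param validate check invariants after loading.
#' @return a `tree_seq` in 1-based closed coordinates.
#' @export
load_treeseq <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 4)
  if (length(magic) == 4 &&
      identical(rawToChar(magic[2:4]), "KAS")) {  # kastore container
    txt <- tempfile(fileext = ".tstxt")
    on.exit(unlink(txt))
    py_convert("to_text", path, txt)
    return(read_treeseq(txt, validate = validate))
  }
  read_treeseq(path, validate = validate)
}

#' Save a tree sequence in the standard binary container format
#'
#' Writes a `.trees` file through the bundled Python/tskit bridge.  Node
#' times that are unknown (`NA`) are replaced by their time-order rank, as
#' the binary format requires numeric times.
#'
#' @param ts a `tree_seq`.
#' @param path output `.trees` path.
#' @return `path`, invisibly.
#' @export
save_trees <- function(ts, path) {
  txt <- tempfile(fileext = ".tstxt")
  on.exit(unlink(txt))
  write_treeseq(ts, txt)
  py_convert("from_text", txt, path)
  invisible(path)
}
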