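# Python bridge: the coalescent simulator and the binary .trees converter
# run through the pre-installed msprime/tskit Python stack.  One process
# per *batch* of simulations, so interpreter start-up is amortised.

py_bin <- function() {
  cached <- getOption("tsabc.python", NULL)
  if (!is.null(cached)) return(cached)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) {
      options(tsabc.python = p)
      return(p)
    }
  }
  stop("no 'python' or 'python3' found on PATH; the coalescent simulator ",
       "requires Python with msprime and tskit")
}

py_script <- function(name) {
  p <- system.file("python", name, package = "tsabc")
  if (!nzchar(p)) {
    # during development (pkgload), inst/ may be unexpanded
    p <- system.file("inst", "python", name, package = "tsabc")
  }
  if (!nzchar(p)) stop("bundled python script not found: ", name)
  p
}

run_py <- function(script, args) {
  out <- suppressWarnings(
    system2(py_bin(), c(shQuote(script), shQuote(args)),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python bridge failed (", script, "):\n",
         paste(utils::tail(out, 15), collapse = "\n"))
  }
  invisible(out)
}

py_convert <- function(mode, src, dst) {
  run_py(py_script("ts_convert.py"), c(mode, src, dst))
  invisible(dst)
}

#' Is the Python msprime/tskit bridge available?
#'
#' @return `TRUE` if a Python interpreter with msprime and tskit is found.
#' @export
have_msprime <- function() {
  cached <- getOption("tsabc.have_msprime", NULL)
  if (!is.null(cached)) return(cached)
  ok <- tryCatch({
    out <- suppressWarnings(system2(
      py_bin(), c("-c", shQuote("import msprime, tskit")),
      stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status")) || attr(out, "status") == 0
  }, error = function(e) FALSE)
  options(tsabc.have_msprime = ok)
  ok
}
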