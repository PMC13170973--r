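#' @keywords internal
#' @noRd
NULL

# gzip is detected by the two magic bytes, never by file extension
isGzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# readLines through the right connection for plain or gzipped text
readTextLines <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  con <- if (isGzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

firstToken <- function(x) sub("[ \t].*$", "", x)

# Reporting-only rounding (internal values keep full precision):
# manifest summary renders depth and breadth at two significant digits,
# the comparative summary table renders depth at two decimals and the
# remaining metrics at the nearest integer.
signif2 <- function(x) signif(x, 2)

round0 <- function(x) round(x, 0)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# run a block with a private RNG stream so callers' .Random.seed survives
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

psLog <- function(..., file = NULL) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  invisible(msg)
}
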