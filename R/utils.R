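#' @useDynLib vctbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft rpois runif sd quantile
#' @importFrom utils modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

stop_contract <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a named, isolated random stream
#'
#' Saves the caller's RNG state, seeds a fresh stream, evaluates `expr`,
#' and restores the state. Every stochastic operator in the toolkit routes
#' its randomness through this helper so that each process (photon noise,
#' dequantization, angle subsampling, bootstrap) owns an independent seed,
#' and a fixed seed gives bitwise-identical output.
#'
#' @param seed integer seed; must not be NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop_contract("a fixed integer seed is required for every stochastic stage")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## full-precision text serialization for numeric arrays: deterministic,
## platform-independent, checksummable
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out[is.nan(x)] <- "NaN"
  out
}

write_array_txt <- function(x, path) {
  d <- dim(x) %||% length(x)
  con <- file(path, open = "wb")  # binary mode: LF endings on all platforms
  on.exit(close(con))
  writeLines(paste0("# dims: ", paste(d, collapse = " ")), con, sep = "\n")
  m <- matrix(format_full(as.vector(x)), nrow = d[1])
  writeLines(apply(m, 1, paste, collapse = "\t"), con, sep = "\n")
  invisible(path)
}

read_array_txt <- function(path) {
  hdr <- readLines(path, n = 1L)
  d <- as.integer(strsplit(sub("^# dims: ", "", hdr), " ")[[1]])
  vals <- scan(path, what = double(), skip = 1L, quiet = TRUE, na.strings = c("NA", "NaN"))
  ## file rows hold x[i, ...]: undo the row-major line layout
  q <- prod(d[-1])
  array(as.vector(t(matrix(vals, nrow = max(q, 1)))), dim = d)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

## raster side normalization: scalar -> square slice, pair -> slice, triple kept
norm_sides <- function(sides) {
  s <- as.integer(sides)
  if (length(s) == 1) s <- c(s, s, 1L)
  else if (length(s) == 2) s <- c(s, 1L)
  if (length(s) != 3 || any(is.na(s)) || any(s <= 0))
    stop_contract("sides must be 1-3 positive integers")
  s
}
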