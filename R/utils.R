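# Internal helpers.

# greatest common divisor / least common multiple over positive integers;
# group sizes are small, so plain Euclid on doubles is exact
gcd2 <- function(a, b) {
  while (b > 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

lcmAll <- function(v) {
  stopifnot(all(v >= 1))
  Reduce(function(a, b) a / gcd2(a, b) * b, as.numeric(v))
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# field delimiter by file extension: tab for .tsv/.txt, comma otherwise
delimFor <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warningf <- function(...) warning(sprintf(...), call. = FALSE)

# expression assay of an SCE / SummarizedExperiment, or a plain matrix
exprValues <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, 1L)
  else x
}

checkExpressionValues <- function(m, what = "expression matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("%s must carry gene and cell identifiers (dimnames)", what)
  if (anyDuplicated(rownames(m)))
    stopf("duplicate gene identifiers in %s", what)
  if (anyDuplicated(colnames(m)))
    stopf("duplicate cell identifiers in %s", what)
  v <- if (methods::is(m, "sparseMatrix")) m@x else m
  if (any(is.na(v)) || any(!is.finite(v)))
    stopf("%s contains missing or non-finite values", what)
  if (any(v < 0))
    stopf("%s contains negative values; expression must be non-negative", what)
  invisible(m)
}

hexFromRgb <- function(m) {
  m <- rbind(m)
  grDevices::rgb(m[, 1], m[, 2], m[, 3])
}
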