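#' @import methods
#' @importFrom stats median pchisq qnorm quantile rbinom rlnorm rnorm runif
#'   setNames p.adjust
#' @importFrom utils write.csv read.csv head tail
#' @importFrom parallel mclapply
#' @importClassesFrom Matrix Matrix
NULL

# Unicode NFKC + whitespace collapse applied to every extracted string.
# Unicode minus (U+2212) and en-dash are preserved here; numeric parsing
# handles them when reading coordinates.
normalizeText <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- gsub("[ \t\r\n ]+", " ", x)
  trimws(x)
}

isAbsent <- function(x) is.null(x) || length(x) == 0L || all(is.na(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable fingerprint of a parameter list: canonical deparse -> md5.
paramsFingerprint <- function(params) {
  params <- params[order(names(params))]
  txt <- paste(
    vapply(names(params), function(nm) {
      paste0(nm, "=", paste(format(params[[nm]], digits = 15), collapse = ","))
    }, character(1)),
    collapse = ";"
  )
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

# Deterministic CSV writer: UTF-8, minimal quoting, LF line endings.
writeCsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n",
            fileEncoding = "UTF-8", na = "")
  invisible(path)
}

# Run an expression with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
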