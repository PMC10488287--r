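#' @keywords internal
"_PACKAGE"

#' @useDynLib sctiger, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor dist median prcomp quantile rbinom rnbinom rnorm runif sd var pnbinom ppois
#' @importFrom utils read.csv read.delim write.csv write.table head
NULL

# derive a reproducible 32-bit sub-seed from a base seed and a stream label
derive_seed <- function(seed, stream) {
  (abs(as.numeric(seed)) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable small integer from a gene identifier (order-free seeding)
name_hash <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  v <- utf8ToInt(as.character(x))
  sum(v * (seq_along(v) %% 7 + 1)) %% 100003
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# emit each distinct warning message at most once per session
.warned <- new.env(parent = emptyenv())
warnf_once <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (is.null(.warned[[msg]])) {
    .warned[[msg]] <- TRUE
    warning(msg, call. = FALSE)
  }
  invisible(NULL)
}
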