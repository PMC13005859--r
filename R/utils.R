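#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom sd cor lm pt pchisq coef logLik predict
#'   plogis runif ave setNames qnorm median
#' @importFrom utils write.table read.table read.csv write.csv head
NULL

# Deterministic derived seeds. Offsets are chosen so that distinct
# (stream, index) pairs never collide for the index ranges used here,
# and the result stays inside 32-bit integer range.
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base)
  mult <- c(100003, 131, 7)[seq_along(idx)]
  s <- s + sum(as.double(idx) * mult)
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards
# (lightweight equivalent of withr::with_seed, hot path of the generator)
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  code
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop_("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
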