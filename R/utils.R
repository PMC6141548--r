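# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

.msg <- function(...) message("[circage] ", sprintf(...))

# Evaluate expr under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# locale-independent, deterministic ordering of ids
sort_c <- function(x) sort(x, method = "radix")

# row-wise sample variance of a numeric matrix (n - 1 denominator)
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("row_vars() needs at least 2 columns")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
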