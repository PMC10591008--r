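# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm pchisq pf pnorm pt ptukey qf qnorm
#'   rnorm runif sd setNames var aggregate complete.cases p.adjust
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit substream seed from a root seed and a label,
# so pipeline stages draw from independent, individually re-runnable streams.
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, ":", as.integer(seed)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647L
  as.integer(h)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x < 1
}

# Resolve a parameter that may be a scalar or a named vector keyed by `keys`.
resolve_by_key <- function(x, keys, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(keys)), keys))
  }
  if (is.null(names(x)) || !all(keys %in% names(x))) {
    stop_config("'%s' must be a scalar or a named vector covering: %s",
                what, paste(keys, collapse = ", "))
  }
  setNames(as.numeric(x[keys]), keys)
}
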