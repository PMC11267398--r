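## internal helpers: seed plumbing and small utilities

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-stream seed
#'
#' Hashes a base seed together with an arbitrary key (e.g. a fish id or a
#' replicate index) into a 31-bit integer seed, so that any subset of a
#' simulated study can be regenerated independently of the rest.
#'
#' @param seed integer base seed.
#' @param ... key components (coerced to character).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "fish", "P01_D")
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

## evaluate `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## stop() with a stage-named, spec-style "configuration error"
config_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

## machine-parseable log line on stderr
log_line <- function(stage, ...) {
  kv <- c(...)
  msg <- paste0("[socresp] stage=", stage,
                if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                                  collapse = " ")) else "")
  message(msg)
  invisible(msg)
}
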