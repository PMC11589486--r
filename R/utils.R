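#' Run code with a temporary RNG seed
#'
#' Evaluates `code` after `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so deterministic generators do not disturb
#' the global RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Clip numeric values to a range
#' @keywords internal
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}
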