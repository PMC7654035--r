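# internal helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_finite <- function(x, name) {
  stop_if(!all(is.finite(x)), sprintf("'%s' must be finite (got %s)",
                                      name, paste(utils::head(x[!is.finite(x)], 3), collapse = ", ")))
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  check_finite(x, name)
  if (strict) stop_if(any(x <= 0), sprintf("'%s' must be > 0", name))
  else stop_if(any(x < 0), sprintf("'%s' must be >= 0", name))
  invisible(x)
}

#' Derive a child seed from a master seed
#'
#' A single run seed fans out deterministically to per-module child seeds so
#' that simulation, observation noise and particle sampling can be re-run
#' independently yet reproducibly. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stream) {
  stop_if(!is.numeric(seed) || length(seed) != 1 || !is.finite(seed),
          "'seed' must be a single finite number")
  as.integer((abs(seed) * 48271 + stream * 2246822519) %% 2147483647)
}

# run a block with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
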