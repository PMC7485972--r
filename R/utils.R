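`%||%` <- function(a, b) if (is.null(a)) b else a

## Min-max rescaling to [0, 1]; a constant vector carries no ranking
## information and maps to 0.5 throughout the package.
unit_rescale <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  if (anyNA(x) || !all(is.finite(x))) {
    stop("cannot rescale: non-finite values present", call. = FALSE)
  }
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-stream seed
#'
#' Hashes a master seed together with an arbitrary sequence of string/numeric
#' tags into a deterministic 31-bit seed. Used by the pipeline so that every
#' stochastic stage (feasibility sampling per network, null sets per
#' interaction) gets its own reproducible stream derived from one master seed.
#'
#' @param master integer master seed.
#' @param ... tags (coerced to character) identifying the sub-stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  tag <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 17
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483629
  as.integer(h) + 1L
}
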