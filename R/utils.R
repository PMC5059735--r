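## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats rnorm rpois runif rgamma sd t.test var
#' @importFrom utils head modifyList read.csv write.csv
NULL

## Classed conditions so callers can distinguish failure modes.
stopc <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "mitomorph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warnc <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(class, "mitomorph_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## Evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

clampRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Recursive list merge: values in `user` override `default`.
mergeConfig <- function(default, user) {
  if (is.null(user)) return(default)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(default[[nm]])) {
      default[[nm]] <- mergeConfig(default[[nm]], user[[nm]])
    } else {
      default[[nm]] <- user[[nm]]
    }
  }
  default
}

isWholeNumber <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
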