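#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and a stream index
#'
#' Keeps every source of randomness attached to one user-visible seed while
#' giving each pipeline stage its own stream. Result stays below 2^31.
#'
#' @param seed master integer seed.
#' @param stream integer stream index (>= 0).
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * (stream + 1)) %% 2147483629)
}

#' Stable hash of a configuration object
#'
#' Serializes the object to canonical JSON and returns its MD5 digest, so
#' re-running an unchanged configuration reproduces the same provenance tag.
#'
#' @param x an R object (list-like).
#' @return character MD5 hash.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
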