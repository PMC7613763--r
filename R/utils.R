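#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' perturb the caller's random stream. `seed = NULL` evaluates the
#' expression with the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic mixing used to give every simulated channel / replicate its
#' own independent stream while staying below 2^31.
#'
#' @param seed master integer seed.
#' @param ... one or more non-negative integer offsets (e.g. replicate index,
#'   channel index).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (o in offs) h <- (h * 48271 + as.numeric(o) * 9973 + 12345) %% 2147483647
  as.integer(h + 1)
}

# recursively sort named components so hashes ignore key order
canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, canonicalize)
  } else x
}

#' Order-insensitive hash of a configuration list
#'
#' Named components are sorted recursively before hashing, so two configs that
#' differ only in key order hash identically.
#'
#' @param config a (possibly nested) named list.
#' @return character scalar (hex digest).
#' @export
config_hash <- function(config) {
  digest::digest(canonicalize(config), algo = "sha1")
}

# linear interpolation of the crossing time between samples i and i+1
.cross_t <- function(t, v, i, level) {
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
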