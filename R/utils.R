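#' @keywords internal
"_PACKAGE"

## Gas constant in kcal mol^-1 K^-1; all free energies in kcal/mol at 25 C.
.R_KCAL <- 1.98720425864083e-3
.T_STANDARD <- 298.15

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a function with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so that library code never perturbs the
#' caller's RNG stream. All stochastic operations in the package route
#' through this helper, which makes them bit-reproducible given a seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## sin(x)/x with the x -> 0 limit handled.
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

assert_nonneg <- function(x, name) {
  assert_scalar_finite(x, name)
  if (x < 0) stop_domain(sprintf("`%s` must be non-negative", name))
  invisible(x)
}

## Stable content hash used to stamp outputs with their configuration.
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

package_version_string <- function() {
  as.character(utils::packageVersion("tabiophys"))
}
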