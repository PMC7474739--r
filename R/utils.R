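`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards, so seeded helpers do not
#' perturb surrounding randomness. A `NULL` seed evaluates `code` as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive independent child seeds from a master seed
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(2147483646L, n))
}

## column variances without an external dependency; NA-tolerant
col_vars <- function(x, na.rm = FALSE) {
  if (na.rm && anyNA(x)) {
    return(apply(x, 2L, stats::var, na.rm = TRUE))
  }
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x * x) - n * mu^2) / (n - 1)
}

stop_field <- function(field, msg) {
  stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0 && x == round(x)
}
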