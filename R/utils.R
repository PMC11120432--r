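#' @importFrom stats pf pnorm ptukey qnorm qlogis plogis dlogis rnorm runif
#'   nlminb optimHess model.matrix cov2cor setNames
#' @importFrom utils modifyList combn write.csv packageVersion
#' @importFrom rlang .data
NULL

# Run `expr` under a fixed seed and restore the caller's RNG state afterwards,
# so seeded simulation functions do not perturb the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic substream derivation: hash(master seed, index) -> seed.
# Kept below 2^31 and within exact double-precision integer arithmetic.
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 1009 + as.numeric(index) * 101203) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a probability strictly between 0 and 1", name),
         call. = FALSE)
  }
  invisible(x)
}
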