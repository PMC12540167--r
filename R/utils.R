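#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All randomness in the package flows through this so that a master seed
# gives bit-identical results regardless of what the caller did before.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream seed from (master seed, stream label, counter), kept well
# below 2^31 so set.seed() accepts it on every platform.
derive_seed <- function(seed, stream, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + counter * 15485863) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) {
  # clamp to avoid exp overflow while keeping the output strictly in (0, 1)
  x <- pmin(pmax(x, -30), 30)
  1 / (1 + exp(-x))
}

relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

elu <- function(x) ifelse(x > 0, x, expm1(x))

elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

# Glorot-style symmetric uniform initialisation.
init_matrix <- function(nrow, ncol) {
  a <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -a, a), nrow, ncol)
}

init_vector <- function(n, fan_in = n) {
  a <- sqrt(6 / (fan_in + 1))
  stats::runif(n, -a, a)
}

# Walk a nested list of numeric arrays and apply f elementwise, preserving
# structure. Used by the optimiser and by gradient accumulation.
map_params <- function(f, ...) {
  args <- list(...)
  x <- args[[1L]]
  if (is.list(x)) {
    out <- vector("list", length(x))
    for (i in seq_along(x)) {
      out[[i]] <- do.call(map_params, c(list(f), lapply(args, `[[`, i)))
    }
    attributes(out) <- attributes(x)   # keep names, merge rules, classes
    out
  } else {
    do.call(f, args)
  }
}

param_zeros_like <- function(params) map_params(function(x) x * 0, params)

flatten_params <- function(params, prefix = "") {
  if (is.list(params)) {
    out <- list()
    nms <- names(params) %||% as.character(seq_along(params))
    for (i in seq_along(params)) {
      out <- c(out, flatten_params(params[[i]],
                                   paste0(prefix, "/", nms[i])))
    }
    out
  } else {
    stats::setNames(list(params), prefix)
  }
}

abort_dim <- function(msg) stop(msg, call. = FALSE)
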