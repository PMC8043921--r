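# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

expit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` after seeding the generator with `seed`, then restores the
#' caller's RNG state, so that every stochastic operation in the package is a
#' pure function of its spec (seed included) without clobbering the session
#' RNG.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derive a per-stage child seed from a master seed (documented counter scheme:
# child = (master * 1000 + offset) mod 2^31-1, kept positive)
child_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000 + offset) %% 2147483647L)
}

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(paste0(...), call. = FALSE)
}

# tiny FNV-1a hash over a serialized object; used to stamp outputs with the
# configuration that produced them without external digest dependencies
config_hash <- function(x) {
  bytes <- as.numeric(serialize(x, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
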