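`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps every stochastic entry point a pure
# function of its seed argument.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# O(1) keyed lookup tables backed by environments.
build_env <- function(keys, values) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  if (length(keys)) {
    list2env(stats::setNames(as.list(as.numeric(values)), keys), envir = e)
  }
  e
}

env_lookup <- function(env, keys) {
  if (is.null(env) || !length(keys)) return(rep(NA_real_, length(keys)))
  vapply(mget(keys, envir = env, ifnotfound = NA_real_), as.numeric,
         numeric(1), USE.NAMES = FALSE)
}

cell_key <- function(...) paste(..., sep = "|")
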