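# internal helpers shared across modules

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-edge substream seed derived from a master seed, so
# resampling results for an edge do not depend on the order edges are visited.
# Kept below 2^31 - 1 (R integers are 32-bit).
edge_seed <- function(seed, i, j) {
  as.integer((as.double(seed) + 131071 * i + 524287 * j) %% 2147483629)
}

# mid-ranks (average ranks on ties)
midranks <- function(x) rank(x, ties.method = "average", na.last = "keep")

is_binary01 <- function(x) {
  (is.numeric(x) && all(x %in% c(0, 1))) || is.logical(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
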