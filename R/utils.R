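#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed from a master seed and a stream name, so each
# generator consumes its own RNG stream and adding a generator never perturbs
# the draws of another. Kept strictly below 2^31 - 1.
sub_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Largest-remainder rounding of a two-way split to one decimal: the pair of
# percentages always reconciles to exactly 100.0.
percent_pair <- function(a, b) {
  stopifnot(a >= 0, b >= 0, a + b > 0)
  tenths <- c(a, b) / (a + b) * 1000
  fl <- floor(tenths)
  left <- 1000 - sum(fl)
  if (left > 0) {
    give <- order(tenths - fl, decreasing = TRUE)[seq_len(left)]
    fl[give] <- fl[give] + 1
  }
  fl / 10
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}
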