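# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG state without clobbering the caller's
# stream. All user-facing randomness goes through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit hash of a string, used to fan a master seed out to
# per-category seeds so one category's stream never depends on which other
# categories are in the run.
string_hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (cp in utf8ToInt(x)) {
    h <- (h * 131 + cp) %% 2147483647
  }
  as.integer(h)
}

derive_seed <- function(master_seed, term_id) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 7919 +
                string_hash31(term_id)) %% 2147483647)
}

# round half away from zero, for reported integer percentages
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
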