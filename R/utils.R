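# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream label; stays below 2^31.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (x in utf8ToInt(parts)) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

# Canonical (sorted) drug-pair order.
canonical_pair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b), swapped = swap)
}

triplet_key <- function(drug_a, drug_b, sample_id) {
  cp <- canonical_pair(drug_a, drug_b)
  paste(cp$a, cp$b, sample_id, sep = "|")
}

stopf <- function(class, fmt, ...) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "combisyn_error"))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == as.integer(x) && x > 0

is_prob <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x <= 1
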