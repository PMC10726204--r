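# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
vi_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "viselect_error")))
}

# Division that maps exact-zero denominators to NA instead of Inf/NaN.
safe_div <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

# Evaluate `code` under a temporary RNG state; the caller's .Random.seed is
# untouched. All stochastic operations in the package route through this so
# there is no dependence on (or pollution of) global random state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = genv)
      } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible sub-seed from a base seed and a counter; stays below
# 2^31 - 1 so it is always a valid R integer seed.
mix_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 2654435761) %% 2147483647)
}

# Exact decimal encoding of doubles for text serialization; 17 significant
# digits round-trip IEEE doubles bit-exactly through as.numeric().
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)

stopifnot_numeric <- function(x, what) {
  if (!is.numeric(x)) vi_stop(sprintf("%s must be numeric", what), "viselect_schema_error")
  invisible(x)
}
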