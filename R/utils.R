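# Internal helpers shared across the package.

# Round half away from zero (counts are nonnegative so this is round-half-up).
# base::round() rounds half to even, which is the wrong quantiser here.
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stable arithmetic hash mapping (root seed, concentration index, replicate
# index) to a per-strip seed in [1, 2^31 - 2]. All intermediates stay below
# 2^53 so double arithmetic is exact.
derive_seed <- function(root, conc_index, rep_index) {
  root <- as.numeric(root) %% 2147483647
  h <- (root * 1000003 + conc_index * 10007 + rep_index * 101) %% 2147483646
  as.integer(h + 1)
}

# Truncated normal on (0, 2]: mean 1, sd `sd`, by rejection. With the small
# sds used for strip jitter the acceptance probability is ~1.
rtruncnorm_unit <- function(sd) {
  if (sd <= 0) return(1)
  repeat {
    x <- stats::rnorm(1, mean = 1, sd = sd)
    if (x > 0 && x <= 2) return(x)
  }
}

stop_lfa <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lfaquant_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
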