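# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed and a small
# component index, so that independent parts of a simulation (trial
# schedule, tonic walk, sweep noise, responses, ...) draw from disjoint,
# individually re-seedable streams.  Kept below 2^31 - 1.
substream <- function(seed, component) {
  s <- (as.numeric(seed) %% 1e6) * 10007 + as.numeric(component) * 97
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# z-score with a guard for zero variance (returns zeros, as downstream
# models treat a constant predictor as "no signal").
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# Signed probit transform of a Welch t statistic: standard normal under
# the null, same sign as t, numerically stable in the far tails via
# log-scale tail probabilities.
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  ok <- is.finite(t)
  z[!ok] <- sign(t[!ok]) * 38
  if (any(ok)) {
    lt <- stats::pt(abs(t[ok]), df[ok], lower.tail = FALSE, log.p = TRUE)
    z[ok] <- -sign(t[ok]) * stats::qnorm(lt, log.p = TRUE)
  }
  pmin(pmax(z, -38), 38)
}

# FNV-1a hash of a character scalar; used to stamp pipeline outputs with
# a config fingerprint without adding a dependency.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
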