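# small internal utilities shared across modules

# classed error helpers so callers can condition on failure type
wk_stop <- function(class, ...) {
  stop(structure(
    class = c(class, "wktap_error", "error", "condition"),
    list(message = sprintf(...), call = sys.call(-1))
  ))
}

wk_format_error <- function(...) wk_stop("wktap_format_error", ...)
wk_record_error <- function(...) wk_stop("wktap_record_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Convert polynomial coefficients b on the basis ((x - center)/scale)^k,
# k = 0..p, to coefficients beta on the raw basis x^k.  Exact for p <= 3
# (and in general): beta_i = sum_{k>=i} b_k scale^{-k} choose(k, i) (-center)^{k-i}.
poly_raw_coefs <- function(b, center, scale = 1) {
  p <- length(b) - 1L
  beta <- numeric(p + 1L)
  for (i in 0:p) {
    acc <- 0
    for (k in i:p) {
      acc <- acc + b[k + 1L] * scale^(-k) * choose(k, i) * (-center)^(k - i)
    }
    beta[i + 1L] <- acc
  }
  names(beta) <- paste0("beta", 0:p)
  beta
}

# Evaluate a polynomial with raw-basis coefficients at x.
poly_eval <- function(beta, x) {
  y <- numeric(length(x))
  for (k in seq_along(beta)) y <- y + beta[k] * x^(k - 1L)
  y
}

# format times at fixed 0.1 ms granularity (deterministic serialization)
format_time_ms <- function(x) sprintf("%.1f", x)
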