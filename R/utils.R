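#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a base seed and a stream index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 2654435761) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_genpred <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_genpred("'%s' must be a single non-missing number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_genpred("'%s' = %g is outside its admissible range %s%g, %g%s",
                 name, x, if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]")
  invisible(x)
}

# Pearson correlation for accuracy reporting: a constant prediction vector
# carries no ranking information, so its accuracy is 0; constant observations
# (or fewer than 3 records) leave the correlation undefined.
safe_cor <- function(obs, pred) {
  if (length(obs) < 3L || stats::sd(obs) == 0) return(NA_real_)
  if (stats::sd(pred) == 0) return(0)
  stats::cor(obs, pred)
}
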