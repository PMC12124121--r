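# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# Two-sided normal p-value for a z statistic; z = 0/0 maps to p = 1 and the
# result is floored at 1e-300 so extreme associations stay in (0, 1].
two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(z)] <- NA_real_
  p[is.nan(z)] <- 1
  pmax(p, 1e-300)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its admissible range", name, x), call. = FALSE)
  invisible(x)
}
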