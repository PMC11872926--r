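# Internal numerical helpers shared across modules.

# Normal critical value for a two-sided CI at `ci_level` (0.95 -> 1.959963985).
z_crit <- function(ci_level) {
  stopifnot(is.numeric(ci_level), length(ci_level) == 1L,
            ci_level > 0, ci_level < 1)
  stats::qnorm(1 - (1 - ci_level) / 2)
}

# Two-sided normal p-value, clamped away from exactly 0 so p stays in (0, 1].
two_sided_p <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream; `seed = NULL` evaluates with the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# scalar checks used by configuration constructors; `name` appears in the
# error so a bad field is identified by name
check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         strict_lo = FALSE, strict_hi = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("invalid configuration: `", name, "` must be a finite numeric scalar",
         call. = FALSE)
  ok_lo <- if (strict_lo) x > lo else x >= lo
  ok_hi <- if (strict_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop("invalid configuration: `", name, "` = ", x, " outside ",
         if (strict_lo) "(" else "[", lo, ", ", hi,
         if (strict_hi) ")" else "]", call. = FALSE)
  if (integer && x != round(x))
    stop("invalid configuration: `", name, "` must be an integer", call. = FALSE)
  invisible(x)
}
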