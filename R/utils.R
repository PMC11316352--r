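#' Round half away from zero
#'
#' Reporting helper: rounds `x` to `digits` decimals with halves going up,
#' matching the conventional presentation of percentages (e.g. 15.85 ->
#' 15.9), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run code with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a master seed and a stream label; kept < 2^31
derive_seed <- function(master_seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop_bad_arg(sprintf("`%s` must be a fraction in %s%g,%g%s",
                                name, if (lo_open) "(" else "[", lo, hi,
                                if (hi_open) ")" else "]"))
  invisible(x)
}
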