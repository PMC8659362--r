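# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rec.601 luma of 8-bit RGB values
#'
#' @param r,g,b numeric vectors/matrices of 8-bit channel values (0--255).
#' @return numeric luma on the same 0--255 scale.
#' @keywords internal
#' @noRd
luma601 <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic derived seed stream; keeps results within 32-bit range.
# (Lehmer-style step in double precision; 48271 * 2^31 < 2^53, so exact.)
derive_seed <- function(seed, k) {
  s <- ((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k)) %% 2147483647
  as.integer(s)
}

is_four_digit_code <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl("^[0-9]{4}$", x)
}

stop_domain <- function(...) stop(..., call. = FALSE)
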