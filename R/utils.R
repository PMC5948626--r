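## Internal helpers shared across modules.

#' @noRd
stop_nircal <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "nircal_error"),
                      call = sys.call(-1)))
}

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
#' @noRd
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
    set.seed(seed)
  }
  force(expr)
}

## Round half away from zero to integer (base round() ties to even, which is
## not how blended concentrations are reported in mg/kg).
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## Tiny stable content hash (FNV-1a, 32 bit) so experiment reports can embed
## a fingerprint of the configuration they were produced from.
#' @noRd
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    ## xor on doubles below 2^32, via two 16-bit halves
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    ## 32-bit modular multiply by the FNV prime, split so intermediates
    ## stay inside exact double-precision integers
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
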