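#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All exported generators route their randomness through this so that equal
# seeds give bitwise-identical results without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# FNV-1a hash of a character scalar, hex string. Used to stamp pipeline
# artifacts with a config fingerprint; not cryptographic.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    h <- h - lo + bitwXor(lo, b %% 65536)
    # multiply by the FNV prime mod 2^32 in two 16-bit halves so every
    # intermediate stays exactly representable in a double
    h <- ((h %% 65536) * p + ((h %/% 65536) * p %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
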