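# Shared internal helpers: classed errors, scoped RNG, seed derivation.

stop_kneedhl <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "kneedhl_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-item stream seed from a master seed. Lehmer-style mixing
# kept below 2^31; all arithmetic stays under 2^53 so doubles are exact.
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- ((master %% m) * 48271 + (index %% m) * 69621 + 1) %% m
  as.integer(s)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# FNV-1a over a character string; returned as hex. Used to stamp artifacts
# with a config fingerprint without an external digest dependency.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 2^31), b)  # b < 256 touches low bits only
    h <- ((lo + (h %/% 2^31) * 2^31) * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
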