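# Internal helpers: validation, seed streams, config hashing.

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# 32-bit FNV-1a hash of a character string, returned as an 8-hex-digit
# string. Arithmetic is done in doubles split into 16-bit halves so the
# 32-bit multiply never loses precision.
fnv1a32 <- function(s) {
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(enc2utf8(s))) {
    # XOR low byte
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    h <- hi * 65536 + lo
    # multiply mod 2^32
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * prime) + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Deterministic child seed from a parent seed and a stream name, kept in
# [0, 2^31 - 1) so it is always a valid R integer seed.
childSeed <- function(seed, stream) {
  stopIfNot(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "'seed' must be a single finite number")
  h <- strtoi(substr(fnv1a32(paste0(stream, ":", seed)), 1, 7), 16L)
  as.integer((abs(seed) + h) %% 2147483647)
}

# Fingerprint of an arbitrary configuration list (serialized as canonical
# JSON, then FNV-1a hashed). Embedded in output metadata so files declare
# the configuration that produced them.
configHash <- function(x) {
  fnv1a32(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
}

# with a local RNG seed, leaving the caller's RNG state untouched
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
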