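# Internal helpers: seeded RNG isolation, child-seed derivation, hashing.

#' Evaluate an expression under a fixed RNG state
#'
#' Runs `code` with the Mersenne-Twister generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded package functions never
#' disturb the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Derive a child seed deterministically from a parent seed and counter
#'
#' Linear-congruential mixing keeps every derived seed inside the 32-bit
#' integer range while making distinct counters give distinct streams.
#' @noRd
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) + 1
  c <- as.double(counter) %% 2147483647
  as.integer((s * 48271 + c * 16807 + 12345) %% 2147483647)
}

# FNV-1a 32-bit hash of a character string, as 8 hex digits. Used for
# config hashes and fixture checksums in run manifests.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply done in two 16-bit halves to stay exact in doubles
    hi <- floor(h / 65536); lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Trapezoidal integral; thin wrapper so all quadrature goes through one place.
trapz_integral <- function(x, y) pracma::trapz(x, y)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_silk <- function(msg, class) {
  stop(structure(class = c(class, "silkphotonics_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
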