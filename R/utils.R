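# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Deterministic sub-stream seed derivation
#'
#' Maps a master seed plus an arbitrary sequence of integer keys to a seed in
#' `[0, 2^31 - 2]` via a modular multiply-add chain (all intermediates stay
#' exactly representable in doubles). Used so that every (plate, well,
#' timepoint) of a simulated screen draws from its own reproducible stream:
#' adding wells or plates to a design never perturbs the events already
#' generated for existing ones.
#'
#' @param master master seed (integer-valued scalar).
#' @param ... integer keys identifying the sub-stream.
#' @return An integer seed suitable for [set.seed()].
#' @examples
#' substream_seed(1, 2, 3) == substream_seed(1, 2, 3)
#' substream_seed(1, 2, 3) != substream_seed(1, 3, 2)
#' @export
substream_seed <- function(master, ...) {
  keys <- c(...)
  if (!is_number(master) || master != floor(master)) {
    stopf("`master` must be an integer-valued scalar")
  }
  # Murmur3-style avalanche mixing on 32-bit words (emulated in doubles).
  # Keys that differ in a single increment must yield unrelated seeds:
  # affinely related seeds give correlated Mersenne-Twister start-up draws,
  # which would couple the plate/replicate effects of fixed well positions.
  two32 <- 4294967296
  mul32 <- function(a, b) {
    # (a * b) mod 2^32, exact: split a into 16-bit halves
    lo <- a %% 65536
    hi <- (a - lo) / 65536
    (lo * b + ((hi * b) %% 65536) * 65536) %% two32
  }
  xor32 <- function(a, b) {
    alo <- a %% 65536; blo <- b %% 65536
    bitwXor(as.integer(alo), as.integer(blo)) +
      bitwXor(as.integer((a - alo) / 65536), as.integer((b - blo) / 65536)) * 65536
  }
  shr <- function(a, n) (a - a %% 2^n) / 2^n
  fmix32 <- function(h) {
    h <- xor32(h, shr(h, 16))
    h <- mul32(h, 2246822507) # 0x85ebca6b
    h <- xor32(h, shr(h, 13))
    h <- mul32(h, 3266489909) # 0xc2b2ae35
    xor32(h, shr(h, 16))
  }
  h <- fmix32(abs(as.numeric(master)) %% two32)
  for (k in as.numeric(keys)) {
    h <- fmix32((h + abs(k) + 2654435769) %% two32) # golden-ratio increment
  }
  as.integer(h %% 2147483647)
}

# evaluate `code` without disturbing the caller-visible RNG state
with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

# microtitre well ids, row-major: A1..A12, B1..B12, ... (columns extended
# beyond 12 for non-standard layouts)
well_ids <- function(n) {
  stopifnot(is_count(n))
  ncols <- max(12L, ceiling(n / 8))
  ids <- paste0(rep(LETTERS[1:8], each = ncols), rep(seq_len(ncols), times = 8))
  ids[seq_len(n)]
}
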