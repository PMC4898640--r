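# Internal helpers: seed sub-streams, age bands, clamping, config hashing.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp values to a range
#'
#' @param x numeric vector.
#' @param bounds length-2 numeric `c(lo, hi)`, or `NULL` for no clamping.
#' @return `x` truncated to `[bounds[1], bounds[2]]`.
#' @keywords internal
clamp <- function(x, bounds) {
  if (is.null(bounds)) return(x)
  pmin(pmax(x, bounds[1]), bounds[2])
}

# Five-year age bands used throughout: "30-34" ... "80-84".
age_band_labels <- function() {
  lo <- seq(30L, 80L, 5L)
  paste(lo, lo + 4L, sep = "-")
}

#' Assign five-year age-band labels
#'
#' Ages are banded into 30-34, 35-39, ..., 80-84. Ages outside 30-84 are
#' clamped into the nearest band (the simulation never holds such ages).
#'
#' @param age integer vector of ages in years.
#' @return character vector of band labels.
#' @export
age_band <- function(age) {
  labs <- age_band_labels()
  idx <- pmin(pmax((as.integer(age) - 30L) %/% 5L + 1L, 1L), length(labs))
  labs[idx]
}

# Deterministic sub-stream seed derivation. Mixes the master seed with any
# number of integer or character tags into a positive integer < 2^31 - 1,
# so every module draws from its own reproducible stream.
substream_seed <- function(master, ...) {
  tags <- list(...)
  h <- as.numeric(master) %% 2147483629
  for (t in tags) {
    if (is.character(t)) t <- sum(utf8ToInt(t)) * 131
    for (v in as.numeric(t)) {
      h <- (h * 48271 + (v %% 2147483629) + 11) %% 2147483629
    }
  }
  as.integer(h %% 2147483629) + 1L
}

# FNV-1a hash over the serialized object; used for config fingerprints in
# run manifests. Version-independent serialization keeps it stable.
config_hash <- function(x) {
  b <- serialize(x, NULL, version = 2)
  b <- as.integer(b[-seq_len(14)])  # drop serialization header
  h <- 2166136261
  for (chunk in split(b, ceiling(seq_along(b) / 4096))) {
    for (v in chunk) {
      h <- bitwXor(as.integer(h %% 2147483647), v)
      h <- (h * 16777619) %% 2147483647
    }
  }
  sprintf("%08x", as.integer(h))
}

# Stop with a configuration-error message naming the offending field.
config_error <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}
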