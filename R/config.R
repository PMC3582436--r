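#' Default fingerprint key
#'
#' A fixed, published 64-bit constant (the golden-ratio word
#' `0x9e3779b97f4a7c15`) used as the default hashing key so that independent
#' parties compute comparable fingerprints out of the box.  Any other key must
#' be agreed out of band: fingerprints are only comparable under identical
#' configurations, key included.
#'
#' @return The key as a decimal string (keys span the full unsigned 64-bit
#'   range, which R doubles cannot represent exactly).
#' @export
#' @examples
#' pfff_default_key()
pfff_default_key <- function() "11400714819323198485"

#' Fingerprint configuration
#'
#' Bundles every parameter that determines the fingerprint function: the
#' hashing key, the number of sampled blocks, the block granularity, whether
#' the file size and a header prefix are mixed into the digest, the
#' compression family and the digest width.  Two fingerprints are comparable
#' if and only if their configurations are identical, which is testable via
#' [config_string()].
#'
#' @param key Hashing key: a non-negative integer (exact up to 2^53) or a
#'   decimal / `0x`-hex string covering the full unsigned 64-bit range.  Seeds
#'   all pseudorandomness: the sampled block positions and the compression
#'   key material.
#' @param samples Number of blocks drawn uniformly with replacement (the
#'   sample count; default 32, which keeps the collision probability below
#'   2^-64 for a million-file collection of variability 0.9 — see
#'   [required_sample_size()]).
#' @param block_size Block granularity in bytes (default 1: blocks are
#'   single bytes).
#' @param include_size Mix the file length (8-byte little-endian) into the
#'   digest?  Default `TRUE`, so files of different lengths never collide;
#'   the variability assumption only speaks about equal-length files.
#' @param header_bytes Length of the file prefix mixed into the digest
#'   (default 0; around 2^20 is a reasonable choice when enabled, since file
#'   headers carry most identifying information).
#' @param family Compression family: `"poly61"` (keyed polynomial evaluation
#'   over GF(2^61 - 1), with a provable almost-universality bound) or
#'   `"crypto"` (truncated SHA-256 of key-then-message).
#' @param digest_bits Digest width: 64 or 128.
#'
#' @return An object of class `pfff_config`.
#' @seealso [pfff_fingerprint()], [config_string()]
#' @export
#' @examples
#' fingerprint_config()
#' fingerprint_config(key = "0xdeadbeef", samples = 11)
fingerprint_config <- function(key = pfff_default_key(),
                               samples = 32L,
                               block_size = 1L,
                               include_size = TRUE,
                               header_bytes = 0L,
                               family = c("poly61", "crypto"),
                               digest_bits = 64L) {
  family <- match.arg(family)
  key <- cpp_key_canonical(key)
  stopifnot(
    "samples must be a single positive integer" =
      is.numeric(samples) && length(samples) == 1 && samples >= 1 &&
      samples == floor(samples),
    "block_size must be a single positive integer" =
      is.numeric(block_size) && length(block_size) == 1 && block_size >= 1 &&
      block_size == floor(block_size),
    "include_size must be TRUE or FALSE" =
      is.logical(include_size) && length(include_size) == 1 &&
      !is.na(include_size),
    "header_bytes must be a single non-negative integer" =
      is.numeric(header_bytes) && length(header_bytes) == 1 &&
      header_bytes >= 0 && header_bytes == floor(header_bytes),
    "digest_bits must be 64 or 128" =
      length(digest_bits) == 1 && digest_bits %in% c(64, 128)
  )
  structure(
    list(key = key, samples = as.integer(samples),
         block_size = as.numeric(block_size),
         include_size = include_size, header_bytes = as.numeric(header_bytes),
         family = family, digest_bits = as.integer(digest_bits)),
    class = "pfff_config"
  )
}

#' Canonical configuration string
#'
#' Serializes a configuration to the canonical form
#' `pfff1;key=<u64>;l=<samples>;b=<block_size>;size=<0|1>;hdr=<H>;fam=<family>;bits=<64|128>`.
#' Digests must only be compared when these strings are equal.
#'
#' @param config A [fingerprint_config()] object.
#' @return A single string.
#' @export
#' @examples
#' config_string(fingerprint_config())
config_string <- function(config) {
  stopifnot(inherits(config, "pfff_config"))
  sprintf("pfff1;key=%s;l=%d;b=%.0f;size=%d;hdr=%.0f;fam=%s;bits=%d",
          config$key, config$samples, config$block_size,
          as.integer(config$include_size), config$header_bytes,
          config$family, config$digest_bits)
}

#' @export
print.pfff_config <- function(x, ...) {
  cat("<pfff_config> ", config_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.pfff_config <- function(x, ...) config_string(x)
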