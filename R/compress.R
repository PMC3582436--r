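#' Deterministic sampled-block positions
#'
#' Draws `samples` block indices uniformly with replacement from
#' `[0, block_count)`, as successive 64-bit Mersenne-twister outputs reduced
#' modulo `block_count`.  Fully deterministic given `(key, block_count,
#' samples)`; duplicate indices are permitted (sampling is with replacement).
#'
#' The fingerprint format reserves the first word of the key's twister stream
#' for compression key material, so [pfff_fingerprint()] draws its indices
#' with `skip = 1`; the default `skip = 0` exposes the raw stream.
#'
#' @param key Hashing key (integer or string, see [fingerprint_config()]).
#' @param block_count Number of blocks in the file (positive; empty files
#'   take the short-file path and never reach index generation).
#' @param samples Number of indices to draw.
#' @param skip Number of leading twister outputs to discard (default 0).
#' @return A numeric vector of `samples` zero-based block indices.
#' @export
#' @examples
#' generate_indices(42, 100, 5)
generate_indices <- function(key, block_count, samples, skip = 0L) {
  cpp_generate_indices(key, as.numeric(block_count), as.integer(samples),
                       as.integer(skip))
}

#' Compress a sample message to a digest
#'
#' The keyed compression stage applied to the assembled message (size field,
#' header prefix and sampled blocks).  A pure function of `(key, message)`.
#'
#' Family `"poly61"` splits the message into 7-byte little-endian chunks
#' `c_0 ... c_{t-1}` (the last chunk zero-padded), evaluates
#' `sum(c_j * r^(t - j)) + t mod (2^61 - 1)` where the evaluation point
#' `r` in `[2, p - 2]` is derived from the key's Mersenne-twister stream, and
#' widens the field element to `digest_bits` with a fixed bijective
#' finalization mix.  Any two fixed messages of at most `L` bytes collide
#' over a random key with probability at most [eps_c_bound()]`(L)`.
#'
#' Family `"crypto"` is the truncated SHA-256 digest of the 8-byte
#' little-endian key followed by the message.
#'
#' @param key Hashing key (integer or string).
#' @param message A raw vector (may be empty).
#' @param family `"poly61"` or `"crypto"`.
#' @param digest_bits Output width, 64 or 128.
#' @return Lowercase hex digest of fixed width `digest_bits / 4`.
#' @export
#' @examples
#' compress_samples(42, charToRaw("some sampled bytes"))
compress_samples <- function(key, message, family = c("poly61", "crypto"),
                             digest_bits = 64L) {
  family <- match.arg(family)
  stopifnot("message must be a raw vector" = is.raw(message),
            "digest_bits must be 64 or 128" = digest_bits %in% c(64, 128))
  if (family == "poly61") {
    cpp_poly61_digest(key, message, as.integer(digest_bits))
  } else {
    h <- openssl::sha256(c(cpp_key_bytes(key), message))
    paste(sprintf("%02x", as.integer(h[seq_len(digest_bits / 8)])),
          collapse = "")
  }
}
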