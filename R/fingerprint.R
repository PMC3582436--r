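num_to_le8 <- function(m) {
  stopifnot(m >= 0, m < 2^53)
  out <- raw(8)
  for (i in 1:8) {
    out[i] <- as.raw(m %% 256)
    m <- m %/% 256
  }
  out
}

#' Probabilistic fast file fingerprint
#'
#' Computes the keyed sampled fingerprint of a file.  With block size `B`,
#' file size `m` and `block_count = ceiling(m / B)` (block `j` spans bytes
#' `[j*B, min((j+1)*B, m))`, so the last block may be short), the digest is
#' the keyed compression of a message assembled from:
#'
#' 1. the file size as an 8-byte little-endian word (if `include_size`);
#' 2. the first `min(header_bytes, m)` bytes (if `header_bytes > 0`);
#' 3. if `m > samples * B`, the `samples` pseudorandomly chosen blocks, in
#'    generation order per [generate_indices()]; otherwise (the short-file
#'    path) the entire file content — reading everything is cheaper than
#'    sampling would be, and any single-byte change is then guaranteed to
#'    change the message.
#'
#' Equal content under an equal configuration yields a byte-identical digest
#' on every platform and backend.  Sampled spans are fetched in ascending
#' offset order (batched into range requests for HTTP sources) but always
#' assembled in generation order.
#'
#' @param source A `pfff_source`, a local path, or an `http(s)://` URL.
#' @param config A [fingerprint_config()].
#' @return A `pfff_fingerprint`: a list with `digest` (lowercase hex),
#'   `config`, `source` (identity) and `size` (bytes).
#' @seealso [pfff_hash()] for the checksum-style vectorized form.
#' @export
#' @examples
#' f <- tempfile(); writeBin(as.raw(sample(0:255, 5000, TRUE)), f)
#' pfff_fingerprint(f)
pfff_fingerprint <- function(source, config = fingerprint_config()) {
  stopifnot(inherits(config, "pfff_config"))
  src <- as_byte_source(source)
  if (!inherits(source, "pfff_source") && inherits(src, "pfff_local_source"))
    on.exit(close(src), add = TRUE)
  m <- source_size(src)
  B <- config$block_size
  message <- raw(0)
  if (config$include_size) message <- num_to_le8(m)
  if (config$header_bytes > 0 && m > 0)
    message <- c(message, read_at(src, 0, min(config$header_bytes, m)))
  if (m > config$samples * B) {
    block_count <- ceiling(m / B)
    idx <- generate_indices(config$key, block_count, config$samples, skip = 1L)
    offsets <- idx * B
    blocks <- read_spans(src, offsets, pmin(B, m - offsets))
    message <- c(message, unlist(blocks, use.names = FALSE))
  } else if (m > 0) {
    message <- c(message, read_at(src, 0, m))
  }
  structure(
    list(digest = compress_samples(config$key, message, config$family,
                                   config$digest_bits),
         config = config, source = source_identity(src), size = m),
    class = "pfff_fingerprint")
}

#' @export
print.pfff_fingerprint <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.pfff_fingerprint <- function(x, ...)
  paste0(x$digest, "  ", x$source)

#' Fingerprint many files, checksum-tool style
#'
#' @param inputs Character vector of paths and/or URLs (or a list of byte
#'   sources).
#' @param config A [fingerprint_config()].
#' @return A named character vector of hex digests (names are the inputs).
#'   Unreadable inputs yield `NA` with a warning.
#' @export
#' @examples
#' f <- tempfile(); writeBin(as.raw(0:255), f)
#' pfff_hash(f)
pfff_hash <- function(inputs, config = fingerprint_config()) {
  out <- vapply(inputs, function(x) {
    tryCatch(pfff_fingerprint(x, config)$digest,
             error = function(e) {
               warning("skipping '", if (is.character(x)) x else
                 source_identity(x), "': ", conditionMessage(e),
                 call. = FALSE)
               NA_character_
             })
  }, "", USE.NAMES = FALSE)
  names(out) <- vapply(inputs, function(x)
    if (is.character(x)) x else source_identity(x), "")
  out
}
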