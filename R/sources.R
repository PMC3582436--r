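#' Random-access byte sources
#'
#' A byte source is a uniform random-access byte provider: a stable size plus
#' a positional `read_at(offset, length)` that returns exactly
#' `min(length, size - offset)` bytes.  Fingerprints are computed through
#' this contract, so a remote file behind an HTTP server that honors range
#' queries is fingerprinted without downloading it.
#'
#' @param x A `pfff_source`, a local path, or an `http(s)://` URL.
#' @param ... Passed to the backend constructor ([open_http()] for URLs).
#' @return A `pfff_source` object.
#' @seealso [open_local()], [open_http()], [read_at()], [read_spans()]
#' @export
as_byte_source <- function(x, ...) {
  if (inherits(x, "pfff_source")) return(x)
  stopifnot("expected a byte source, a path, or a URL" =
              is.character(x) && length(x) == 1)
  if (grepl("^https?://", x)) open_http(x, ...) else open_local(x)
}

#' Open a local file as a byte source
#'
#' @param path Path to an existing regular file.
#' @return A `pfff_local_source`.  Reads are positional (no shared cursor),
#'   so out-of-order and repeated reads are safe.
#' @export
#' @examples
#' f <- tempfile(); writeBin(as.raw(0:9), f)
#' src <- open_local(f)
#' source_size(src)
#' read_at(src, 8, 10)  # clamped to the last 2 bytes
open_local <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop("not a readable file: '", path, "'")
  size <- file.size(path)
  con <- file(path, open = "rb")
  env <- new.env(parent = emptyenv())
  env$con <- con
  structure(list(identity = path, size = as.numeric(size), state = env),
            class = c("pfff_local_source", "pfff_source"))
}

#' Open a remote file over HTTP(S) as a byte source
#'
#' Discovers the size from the `Content-Length` header of a HEAD request and
#' serves `read_at` through byte-range requests (`Range: bytes=a-b`).  A
#' batched [read_spans()] first issues one multi-range request and parses the
#' `multipart/byteranges` answer; if the server replies with the full body
#' instead, it falls back to one request per span.
#'
#' @param url An `http://` or `https://` URL.
#' @param range_policy `"require"` fails when the server ignores range
#'   requests; `"fallback-full"` downloads the body once and serves reads
#'   from the cached copy (correct, but forfeits the sampling speedup).
#' @param retries Number of extra attempts per request on transport errors.
#' @return A `pfff_http_source`.
#' @export
open_http <- function(url, range_policy = c("require", "fallback-full"),
                      retries = 1L) {
  range_policy <- match.arg(range_policy)
  env <- new.env(parent = emptyenv())
  env$full_body <- NULL
  src <- structure(
    list(identity = url, size = NA_real_, policy = range_policy,
         retries = as.integer(retries), state = env),
    class = c("pfff_http_source", "pfff_source"))
  head <- http_request(src, nobody = TRUE)
  len <- head$headers[["content-length"]]
  if (is.null(len)) {
    if (range_policy == "require")
      stop("server for '", url, "' reports no Content-Length; ",
           "size is required for sampling - use range_policy = ",
           "\"fallback-full\" to scan the full body instead")
    env$full_body <- http_request(src)$content
    src$size <- as.numeric(length(env$full_body))
  } else {
    src$size <- as.numeric(len)
  }
  src
}

#' Read bytes at an offset
#'
#' @param src A `pfff_source`.
#' @param offset Zero-based byte offset.
#' @param length Number of bytes requested.
#' @return A raw vector of `min(length, size - offset)` bytes (empty when
#'   `offset >= size`).
#' @export
read_at <- function(src, offset, length) UseMethod("read_at")

#' Read many byte spans
#'
#' Backend-aware batched read: spans are fetched in ascending offset order
#' (adjacent and overlapping spans coalesced into single requests) but the
#' result list is returned in input order, which is what the fingerprint's
#' message assembly requires.
#'
#' @param src A `pfff_source`.
#' @param offsets,lengths Equal-length numeric vectors of zero-based offsets
#'   and span lengths.
#' @return A list of raw vectors, one per input span, each clamped to the
#'   source size.
#' @export
read_spans <- function(src, offsets, lengths) UseMethod("read_spans")

#' Source size in bytes
#' @param src A `pfff_source`.
#' @return A number.
#' @export
source_size <- function(src) UseMethod("source_size")

#' Source identity (path or URL)
#' @param src A `pfff_source`.
#' @return A string.
#' @export
source_identity <- function(src) UseMethod("source_identity")

#' @export
source_size.pfff_source <- function(src) src$size

#' @export
source_identity.pfff_source <- function(src) src$identity

#' @export
print.pfff_source <- function(x, ...) {
  cat("<byte source> ", x$identity, " (", format(x$size, big.mark = ","),
      " bytes)\n", sep = "")
  invisible(x)
}

clamp_span <- function(src, offset, length) {
  stopifnot(offset >= 0, length >= 0)
  max(0, min(length, src$size - offset))
}

#' @export
read_at.pfff_local_source <- function(src, offset, length) {
  n <- clamp_span(src, offset, length)
  if (n == 0) return(raw(0))
  con <- src$state$con
  if (!isOpen(con)) {  # reopen transparently, e.g. after deserialization
    con <- file(src$identity, open = "rb")
    src$state$con <- con
  }
  seek(con, where = offset, origin = "start")
  readBin(con, "raw", n = n)
}

#' @export
read_spans.pfff_source <- function(src, offsets, lengths) {
  stopifnot(length(offsets) == length(lengths))
  ord <- order(offsets)  # ascending offsets: cheap on rotational media
  out <- vector("list", length(offsets))
  for (i in ord) out[[i]] <- read_at(src, offsets[i], lengths[i])
  out
}

#' Close a byte source
#' @param con A `pfff_local_source`.
#' @param ... Ignored.
#' @export
close.pfff_local_source <- function(con, ...) {
  if (isOpen(con$state$con)) close(con$state$con)
  invisible(NULL)
}

# --- HTTP plumbing ---------------------------------------------------------

http_request <- function(src, range = NULL, nobody = FALSE) {
  h <- curl::new_handle(nobody = nobody)
  if (!is.null(range))
    curl::handle_setheaders(h, Range = paste0("bytes=", range))
  last <- NULL
  for (attempt in seq_len(src$retries + 1L)) {
    resp <- tryCatch(curl::curl_fetch_memory(src$identity, handle = h),
                     error = identity)
    if (!inherits(resp, "error")) {
      resp$headers <- curl::parse_headers_list(resp$headers)
      return(resp)
    }
    last <- resp
  }
  stop("request to '", src$identity, "' failed: ", conditionMessage(last))
}

#' @export
read_at.pfff_http_source <- function(src, offset, length) {
  n <- clamp_span(src, offset, length)
  if (n == 0) return(raw(0))
  if (!is.null(src$state$full_body))
    return(src$state$full_body[(offset + 1):(offset + n)])
  resp <- http_request(src, range = sprintf("%.0f-%.0f", offset, offset + n - 1))
  if (resp$status_code == 206) {
    body <- resp$content
    if (length(body) != n)
      stop("server for '", src$identity, "' returned ", length(body),
           " bytes for a ", n, "-byte range")
    return(body)
  }
  if (resp$status_code == 200) {
    if (src$policy == "require")
      stop("server for '", src$identity, "' ignores Range requests ",
           "(answered 200 with the full body); use range_policy = ",
           "\"fallback-full\" to allow a one-time full scan")
    src$state$full_body <- resp$content
    return(resp$content[(offset + 1):(offset + n)])
  }
  stop("server for '", src$identity, "' answered HTTP ", resp$status_code)
}

# Merge ascending clamped spans into maximal runs; adjacent or overlapping
# spans become one request.
coalesce_spans <- function(offsets, lengths) {
  ord <- order(offsets)
  runs <- list()
  cur_start <- cur_end <- NULL
  for (i in ord) {
    s <- offsets[i]; e <- offsets[i] + lengths[i]
    if (is.null(cur_start)) {
      cur_start <- s; cur_end <- e
    } else if (s <= cur_end) {
      cur_end <- max(cur_end, e)
    } else {
      runs[[length(runs) + 1L]] <- c(cur_start, cur_end)
      cur_start <- s; cur_end <- e
    }
  }
  if (!is.null(cur_start)) runs[[length(runs) + 1L]] <- c(cur_start, cur_end)
  runs
}

parse_multipart_byteranges <- function(body, content_type) {
  m <- regmatches(content_type,
                  regexec("boundary=\"?([^\";]+)\"?", content_type))[[1]]
  if (length(m) < 2) return(NULL)
  delim <- charToRaw(paste0("--", m[2]))
  hits <- grepRaw(delim, body, all = TRUE, fixed = TRUE)
  if (length(hits) < 2) return(NULL)
  crlf2 <- charToRaw("\r\n\r\n")
  parts <- list()
  for (i in seq_len(length(hits) - 1L)) {
    seg <- body[hits[i]:(hits[i + 1] - 1L)]
    hdr_end <- grepRaw(crlf2, seg, fixed = TRUE)
    if (length(hdr_end) == 0) next
    headers <- strsplit(rawToChar(seg[seq_len(hdr_end + 3L)]), "\r\n")[[1]]
    cr <- grep("^content-range:", headers, ignore.case = TRUE, value = TRUE)
    if (length(cr) == 0) next
    rng <- regmatches(cr[1], regexec("bytes ([0-9]+)-([0-9]+)/", cr[1]))[[1]]
    if (length(rng) < 3) next
    data <- seg[(hdr_end + 4L):length(seg)]
    # strip the trailing CRLF that precedes the next delimiter
    nd <- length(data)
    if (nd >= 2 && data[nd - 1L] == as.raw(13L) && data[nd] == as.raw(10L))
      data <- data[seq_len(nd - 2L)]
    parts[[length(parts) + 1L]] <-
      list(start = as.numeric(rng[2]), end = as.numeric(rng[3]), data = data)
  }
  parts
}

slice_from_runs <- function(run_data, offsets, lengths) {
  out <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    n <- lengths[i]
    if (n == 0) { out[[i]] <- raw(0); next }
    for (rd in run_data) {
      if (offsets[i] >= rd$start && offsets[i] + n <= rd$end) {
        a <- offsets[i] - rd$start
        out[[i]] <- rd$data[(a + 1):(a + n)]
        break
      }
    }
    if (is.null(out[[i]])) stop("internal: span not covered by fetched runs")
  }
  out
}

#' @export
read_spans.pfff_http_source <- function(src, offsets, lengths) {
  stopifnot(length(offsets) == length(lengths))
  lengths <- pmin(lengths, pmax(0, src$size - offsets))
  if (!is.null(src$state$full_body) || length(offsets) <= 1L)
    return(NextMethod())
  runs <- coalesce_spans(offsets[lengths > 0], lengths[lengths > 0])
  if (length(runs) == 0) return(rep(list(raw(0)), length(offsets)))
  if (length(runs) == 1L) {
    rd <- list(list(start = runs[[1]][1], end = runs[[1]][2],
                    data = read_at(src, runs[[1]][1],
                                   runs[[1]][2] - runs[[1]][1])))
    return(slice_from_runs(rd, offsets, lengths))
  }
  spec <- paste(vapply(runs, function(r) sprintf("%.0f-%.0f", r[1], r[2] - 1),
                       ""), collapse = ",")
  resp <- http_request(src, range = spec)
  if (resp$status_code == 206) {
    ctype <- resp$headers[["content-type"]]
    if (!is.null(ctype) && grepl("multipart/byteranges", ctype)) {
      parts <- parse_multipart_byteranges(resp$content, ctype)
      if (!is.null(parts) && length(parts) == length(runs)) {
        rd <- lapply(parts, function(p)
          list(start = p$start, end = p$end + 1, data = p$data))
        return(slice_from_runs(rd, offsets, lengths))
      }
    }
    # 206 but a single (first) range: fall through to per-span requests
  }
  if (resp$status_code == 200 && src$policy == "fallback-full") {
    src$state$full_body <- resp$content
  }
  # per-span fallback (read_at handles policy checks and full-body cache)
  NextMethod()
}
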