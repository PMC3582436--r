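# Minimal HTTP/1.1 fixture server run in a background R process (callr).
# Implemented on base-R server sockets so tests fully control the response
# headers: single and multipart byte ranges, range-ignoring mode, and a
# mode that omits Content-Length.  Every request is appended to a log file
# as "METHOD path range" so tests can count requests.
#
# modes:
#   "multirange" - honors single and multi-range requests (206)
#   "single"     - honors single ranges; multi-range answered 200 full body
#   "noranges"   - ignores Range entirely (always 200 full body)
#   "nolength"   - like "single" but never sends Content-Length

fixture_server_fun <- function(dir, port, mode, log) {
  crlf <- "\r\n"
  respond <- function(con, status, headers, body = raw(0)) {
    hdr <- paste0("HTTP/1.1 ", status, crlf,
                  paste0(names(headers), ": ", unlist(headers),
                         collapse = crlf),
                  crlf, crlf)
    writeBin(charToRaw(hdr), con)
    if (length(body)) writeBin(body, con)
    flush(con)
  }
  parse_ranges <- function(spec, size) {
    spec <- sub("^bytes=", "", spec)
    out <- list()
    for (part in strsplit(spec, ",")[[1]]) {
      m <- regmatches(part, regexec("^([0-9]+)-([0-9]+)$", part))[[1]]
      if (length(m) < 3) return(NULL)
      a <- as.numeric(m[2]); b <- min(as.numeric(m[3]), size - 1)
      if (a > b) return(NULL)
      out[[length(out) + 1L]] <- c(a, b)
    }
    out
  }
  srv <- serverSocket(port)
  on.exit(close(srv))
  writeLines("ready", paste0(log, ".ready"))
  repeat {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 600)
    ok <- tryCatch({
      req <- readLines(con, 1)
      if (length(req) == 0) { close(con); next }
      range <- NULL
      repeat {
        h <- readLines(con, 1)
        if (length(h) == 0 || h == "") break
        if (grepl("^[Rr]ange:", h)) range <- sub("^[Rr]ange:\\s*", "", h)
      }
      parts <- strsplit(req, " ")[[1]]
      method <- parts[1]
      path <- utils::URLdecode(parts[2])
      cat(sprintf("%s %s %s\n", method, path,
                  if (is.null(range)) "-" else range),
          file = log, append = TRUE)
      f <- file.path(dir, substring(path, 2))
      if (!file.exists(f) || dir.exists(f)) {
        respond(con, "404 Not Found",
                list("Content-Length" = "0", "Connection" = "close"))
        close(con); next
      }
      size <- file.size(f)
      base_headers <- list("Accept-Ranges" = "bytes", "Connection" = "close",
                           "Content-Type" = "application/octet-stream")
      if (method == "HEAD") {
        h <- base_headers
        if (mode != "nolength") h[["Content-Length"]] <- sprintf("%.0f", size)
        respond(con, "200 OK", h)
        close(con); next
      }
      content <- readBin(f, "raw", size)
      ranges <- if (!is.null(range) && mode != "noranges")
        parse_ranges(range, size) else NULL
      if (is.null(ranges) ||
          (length(ranges) > 1 && mode != "multirange")) {
        h <- base_headers
        if (mode != "nolength")
          h[["Content-Length"]] <- sprintf("%.0f", length(content))
        respond(con, "200 OK", h, content)
      } else if (length(ranges) == 1) {
        a <- ranges[[1]][1]; b <- ranges[[1]][2]
        body <- content[(a + 1):(b + 1)]
        h <- base_headers
        h[["Content-Range"]] <- sprintf("bytes %.0f-%.0f/%.0f", a, b, size)
        h[["Content-Length"]] <- sprintf("%d", length(body))
        respond(con, "206 Partial Content", h, body)
      } else {
        bnd <- "pffffixturebnd"
        body <- raw(0)
        for (r in ranges) {
          part <- paste0("--", bnd, crlf,
                         "Content-Type: application/octet-stream", crlf,
                         sprintf("Content-Range: bytes %.0f-%.0f/%.0f",
                                 r[1], r[2], size), crlf, crlf)
          body <- c(body, charToRaw(part),
                    content[(r[1] + 1):(r[2] + 1)], charToRaw(crlf))
        }
        body <- c(body, charToRaw(paste0("--", bnd, "--", crlf)))
        h <- base_headers
        h[["Content-Type"]] <-
          paste0("multipart/byteranges; boundary=", bnd)
        h[["Content-Length"]] <- sprintf("%d", length(body))
        respond(con, "206 Partial Content", h, body)
      }
      close(con)
      TRUE
    }, error = function(e) { try(close(con), silent = TRUE); TRUE })
  }
}

start_fixture_server <- function(dir, mode = "multirange") {
  log <- tempfile("httplog_")
  file.create(log)
  for (attempt in 1:10) {
    port <- sample(20000:59999, 1)
    proc <- callr::r_bg(fixture_server_fun,
                        args = list(dir = dir, port = port, mode = mode,
                                    log = log),
                        supervise = TRUE)
    for (i in 1:100) {
      if (file.exists(paste0(log, ".ready"))) break
      if (!proc$is_alive()) break
      Sys.sleep(0.05)
    }
    if (proc$is_alive() && file.exists(paste0(log, ".ready"))) {
      unlink(paste0(log, ".ready"))
      return(list(proc = proc, port = port, log = log,
                  url = function(name) sprintf("http://127.0.0.1:%d/%s",
                                               port, name)))
    }
    proc$kill()
  }
  stop("could not start fixture server")
}

stop_fixture_server <- function(srv) {
  srv$proc$kill()
}

request_log <- function(srv) {
  if (!file.exists(srv$log)) return(character(0))
  readLines(srv$log, warn = FALSE)
}
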