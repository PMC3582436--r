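test_that("local sources give positional clamped reads", {
  f <- write_bytes(as.raw(0:9))
  src <- open_local(f)
  on.exit(close(src))
  expect_identical(source_size(src), 10)
  expect_identical(read_at(src, 0, 10), as.raw(0:9))
  expect_identical(read_at(src, 8, 10), as.raw(8:9))   # clamped
  expect_identical(read_at(src, 10, 1), raw(0))        # boundary
  expect_identical(read_at(src, 0, 100), as.raw(0:9))
  # out-of-order reads are safe (no shared cursor semantics)
  expect_identical(read_at(src, 5, 2), as.raw(5:6))
  expect_identical(read_at(src, 0, 2), as.raw(0:1))
  expect_error(open_local(file.path(tempdir(), "absent")), "absent")
})

test_that("span batching returns input order whatever the fetch order", {
  f <- write_bytes(as.raw(0:99))
  src <- open_local(f)
  on.exit(close(src))
  offs <- c(90, 0, 50, 10, 50)
  got <- read_spans(src, offs, rep(5, 5))
  expect_identical(got, lapply(offs, function(o) as.raw(o:(o + 4))))
})

test_that("adjacent and overlapping spans coalesce into single runs", {
  co <- pfff:::coalesce_spans(c(0, 5, 20, 18), c(5, 5, 4, 3))
  expect_identical(co, list(c(0, 10), c(18, 24)))
  expect_identical(pfff:::coalesce_spans(c(7), c(3)), list(c(7, 10)))
})

test_that("HTTP sources read byte-identically to local ones", {
  dir <- tempfile("httpfix_"); dir.create(dir)
  content <- pfff:::with_local_seed(31, pfff:::random_bytes(5000))
  writeBin(content, file.path(dir, "data.bin"))
  srv <- start_fixture_server(dir, mode = "multirange")
  on.exit(stop_fixture_server(srv))
  h <- open_http(srv$url("data.bin"))
  l <- open_local(file.path(dir, "data.bin"))
  on.exit(close(l), add = TRUE)
  expect_identical(source_size(h), 5000)
  for (span in list(c(0, 10), c(4990, 10), c(4995, 100), c(5000, 5),
                    c(1234, 1)))
    expect_identical(read_at(h, span[1], span[2]),
                     read_at(l, span[1], span[2]))
  offs <- c(4000, 0, 17, 2500, 18)
  expect_identical(read_spans(h, offs, rep(9, 5)),
                   read_spans(l, offs, rep(9, 5)))
})

test_that("batched spans use one multi-range request when honored", {
  dir <- tempfile("httpfix_"); dir.create(dir)
  writeBin(pfff:::with_local_seed(32, pfff:::random_bytes(4000)),
           file.path(dir, "f.bin"))
  srv <- start_fixture_server(dir, mode = "multirange")
  on.exit(stop_fixture_server(srv))
  h <- open_http(srv$url("f.bin"))
  n0 <- length(request_log(srv))
  got <- read_spans(h, c(10, 500, 2000, 3999), c(5, 5, 5, 5))
  expect_identical(got[[4]], read_at(h, 3999, 5))
  gets <- grep("^GET", request_log(srv), value = TRUE)
  expect_identical(length(request_log(srv)), n0 + 2L)  # 1 batched + 1 check
})

test_that("multi-range refusal falls back to per-span requests", {
  dir <- tempfile("httpfix_"); dir.create(dir)
  writeBin(pfff:::with_local_seed(33, pfff:::random_bytes(4000)),
           file.path(dir, "f.bin"))
  srv <- start_fixture_server(dir, mode = "single")
  on.exit(stop_fixture_server(srv))
  h <- open_http(srv$url("f.bin"))
  offs <- c(10, 500, 2000, 3000)
  got <- read_spans(h, offs, rep(5, 4))
  expect_identical(got, lapply(offs, function(o) read_at(h, o, 5)))
  # at most 1 + number-of-spans GET requests for the batched read
  gets <- grep("^GET", request_log(srv), value = TRUE)
  expect_lte(length(gets), 1 + 4 + 4)  # batched attempt + fallbacks + checks
})

test_that("servers that ignore ranges obey the range policy", {
  dir <- tempfile("httpfix_"); dir.create(dir)
  content <- pfff:::with_local_seed(34, pfff:::random_bytes(2000))
  writeBin(content, file.path(dir, "f.bin"))
  srv <- start_fixture_server(dir, mode = "noranges")
  on.exit(stop_fixture_server(srv))
  strict <- open_http(srv$url("f.bin"), range_policy = "require")
  expect_error(read_at(strict, 10, 5), "ignores Range")
  lax <- open_http(srv$url("f.bin"), range_policy = "fallback-full")
  expect_identical(read_at(lax, 10, 5), content[11:15])
  expect_identical(read_at(lax, 1990, 100), content[1991:2000])
})

test_that("a missing Content-Length requires explicit full-scan consent", {
  dir <- tempfile("httpfix_"); dir.create(dir)
  content <- pfff:::with_local_seed(35, pfff:::random_bytes(999))
  writeBin(content, file.path(dir, "f.bin"))
  srv <- start_fixture_server(dir, mode = "nolength")
  on.exit(stop_fixture_server(srv))
  expect_error(open_http(srv$url("f.bin"), range_policy = "require"),
               "full-scan|fallback-full")
  lax <- open_http(srv$url("f.bin"), range_policy = "fallback-full")
  expect_identical(source_size(lax), 999)
  expect_identical(read_at(lax, 0, 999), content)
})

test_that("fingerprints agree between local and HTTP backends", {
  dir <- tempfile("httpfix_"); dir.create(dir)
  sizes <- c(0, 1, 10, 31, 32, 33, 100, 1000)
  for (i in seq_along(sizes))
    writeBin(pfff:::with_local_seed(40 + i, pfff:::random_bytes(sizes[i])),
             file.path(dir, sprintf("s%d.bin", sizes[i])))
  srv <- start_fixture_server(dir, mode = "multirange")
  on.exit(stop_fixture_server(srv))
  for (cfg in list(fingerprint_config(),
                   fingerprint_config(key = 5, samples = 7, block_size = 16,
                                      header_bytes = 20))) {
    for (s in sizes) {
      name <- sprintf("s%d.bin", s)
      local_fp <- pfff_fingerprint(file.path(dir, name), cfg)
      http_fp <- pfff_fingerprint(open_http(srv$url(name)), cfg)
      expect_identical(http_fp$digest, local_fp$digest)
    }
  }
})
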