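test_that("short-file path hashes size field plus entire content", {
  f <- write_bytes(as.raw(0:9))
  cfg <- fingerprint_config(key = 7)  # 10 bytes <= 32 samples * 1 byte
  fp <- pfff_fingerprint(f, cfg)
  expect_identical(fp$digest, "af23e862e6e51dc7")  # big-integer reference
  # equals the compression of 8-byte little-endian size followed by content
  manual <- compress_samples(7, c(pfff:::num_to_le8(10), as.raw(0:9)))
  expect_identical(fp$digest, manual)
  expect_identical(fp$size, 10)
})

test_that("empty file fingerprints to the compressed size field alone", {
  f <- write_bytes(raw(0))
  fp <- pfff_fingerprint(f, fingerprint_config(key = 3))
  expect_identical(fp$digest, compress_samples(3, pfff:::num_to_le8(0)))
  # without the size field the message is empty and must not crash
  fp2 <- pfff_fingerprint(f, fingerprint_config(key = 3,
                                                include_size = FALSE))
  expect_identical(fp2$digest, compress_samples(3, raw(0)))
})

test_that("sampled path assembles blocks in generation order", {
  cfg <- fingerprint_config(key = 99, samples = 8, block_size = 3)
  content <- pfff:::with_local_seed(2, pfff:::random_bytes(1000))
  f <- write_bytes(content)
  m <- 1000; bc <- ceiling(m / 3)
  idx <- generate_indices(99, bc, 8, skip = 1)
  blocks <- lapply(idx, function(j)
    content[(j * 3 + 1):min((j + 1) * 3, m)])
  manual <- compress_samples(
    99, c(pfff:::num_to_le8(m), unlist(blocks)))
  expect_identical(pfff_fingerprint(f, cfg)$digest, manual)
})

test_that("the last block may be short and is hashed as-is", {
  content <- pfff:::with_local_seed(3, pfff:::random_bytes(100))
  f <- write_bytes(content)  # 100 bytes, block_size 7 -> 15 blocks, last 2
  cfg <- fingerprint_config(key = 5, samples = 4, block_size = 7)
  idx <- generate_indices(5, 15, 4, skip = 1)
  blocks <- lapply(idx, function(j)
    content[(j * 7 + 1):min((j + 1) * 7, 100)])
  manual <- compress_samples(5, c(pfff:::num_to_le8(100), unlist(blocks)))
  expect_identical(pfff_fingerprint(f, cfg)$digest, manual)
})

test_that("header prefix is mixed into the digest when requested", {
  content <- pfff:::with_local_seed(4, pfff:::random_bytes(500))
  f <- write_bytes(content)
  cfg <- fingerprint_config(key = 1, samples = 4, header_bytes = 64)
  idx <- generate_indices(1, 500, 4, skip = 1)
  manual <- compress_samples(
    1, c(pfff:::num_to_le8(500), content[1:64], content[idx + 1]))
  expect_identical(pfff_fingerprint(f, cfg)$digest, manual)
  # header request longer than the file clamps to the whole file
  g <- write_bytes(as.raw(1:5))
  cfg2 <- fingerprint_config(key = 1, samples = 8, header_bytes = 1e6)
  fp <- pfff_fingerprint(g, cfg2)
  # short-file path (5 bytes < 8 samples): header then full content
  manual2 <- compress_samples(1, c(pfff:::num_to_le8(5), as.raw(1:5),
                                   as.raw(1:5)))
  expect_identical(fp$digest, manual2)
})

test_that("files of different sizes never share a digest when size is included", {
  set.seed(8)
  digests <- vapply(c(10, 11, 100, 1000, 5000), function(n)
    pfff_fingerprint(write_bytes(pfff:::random_bytes(n)))$digest, "")
  expect_identical(anyDuplicated(digests), 0L)
})

test_that("fingerprints are reproducible across runs and configs differ", {
  f <- rand_file(4096, seed = 21)
  cfgs <- list(
    fingerprint_config(),
    fingerprint_config(key = "0x1234abcd"),
    fingerprint_config(samples = 11),
    fingerprint_config(block_size = 512),
    fingerprint_config(family = "crypto"),
    fingerprint_config(digest_bits = 128),
    fingerprint_config(include_size = FALSE),
    fingerprint_config(header_bytes = 100)
  )
  d1 <- vapply(cfgs, function(cfg) pfff_fingerprint(f, cfg)$digest, "")
  d2 <- vapply(cfgs, function(cfg) pfff_fingerprint(f, cfg)$digest, "")
  expect_identical(d1, d2)
  expect_identical(anyDuplicated(d1), 0L)  # each config is its own function
  strs <- vapply(cfgs, config_string, "")
  expect_identical(anyDuplicated(strs), 0L)
})

test_that("single-byte changes below the sampled volume always change the digest", {
  cfg <- fingerprint_config(key = 17, samples = 64)
  content <- pfff:::with_local_seed(6, pfff:::random_bytes(50))
  base <- pfff_fingerprint(write_bytes(content), cfg)$digest
  for (pos in c(1, 17, 50)) {
    tweaked <- content
    tweaked[pos] <- xor(tweaked[pos], as.raw(1))
    expect_false(pfff_fingerprint(write_bytes(tweaked), cfg)$digest == base)
  }
})

test_that("empirical pair-collision rate matches the with-replacement closed form", {
  # 10 blocks, 5 differing, 3 samples: collision probability 0.5^3 = 0.125
  spec <- synthetic_spec(1000, delta = 0.5, block_size = 100, seed = 9)
  pair <- make_pair(spec)
  cfg_for <- function(k) fingerprint_config(key = k, samples = 3,
                                            block_size = 100)
  keys <- pfff:::with_local_seed(10, sample.int(.Machine$integer.max, 400))
  hits <- sum(vapply(keys, function(k) {
    cfg <- cfg_for(k)
    pfff_fingerprint(pair$file_a, cfg)$digest ==
      pfff_fingerprint(pair$file_b, cfg)$digest
  }, NA))
  ci <- qbinom(c(0.005, 0.995), 400, 0.125)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("unreadable sources fail with the source named", {
  expect_error(pfff_fingerprint(file.path(tempdir(), "no-such-file")),
               "no-such-file")
  expect_warning(out <- pfff_hash(c(rand_file(10, 1), "missing-file")),
                 "missing-file")
  expect_identical(sum(is.na(out)), 1L)
})
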