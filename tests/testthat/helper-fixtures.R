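# Programmatic fixtures: everything is generated at test time.

write_bytes <- function(bytes, path = tempfile()) {
  writeBin(bytes, path)
  path
}

rand_file <- function(n, seed, dir = NULL) {
  path <- if (is.null(dir)) tempfile() else tempfile(tmpdir = dir)
  pfff:::with_local_seed(seed, writeBin(pfff:::random_bytes(n), path))
  path
}

# A varied suite of files exercising every code path: empty, 1-byte,
# below the sampled volume (short-file path), exactly at the threshold,
# and multi-block files of assorted sizes.
fixture_suite <- function(dir = tempfile("suite_"), samples = 32) {
  dir.create(dir)
  sizes <- c(0, 1, 2, 7, 8, 9, samples - 1, samples, samples + 1,
             63, 64, 65, 100, 127, 128, 129, 255, 256, 257,
             round(seq(300, 5000, length.out = 32)))
  paths <- character(0)
  for (i in seq_along(sizes)) {
    p <- file.path(dir, sprintf("f%02d_%d.bin", i, sizes[i]))
    pfff:::with_local_seed(1000 + i,
      writeBin(pfff:::random_bytes(sizes[i]), p))
    paths <- c(paths, p)
  }
  paths
}
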