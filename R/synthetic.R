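#' Specification for a synthetic file collection
#'
#' Ground-truth generator parameters: files of `base_size` random bytes at
#' block granularity `block_size`, with pairwise variability controlled
#' exactly (for generated pairs) at `delta`.  Everything is deterministic
#' given `seed`, and the generator's random stream is independent of the
#' fingerprint key stream, so collision experiments over keys are run
#' against fixed content.
#'
#' @param base_size File size in bytes.
#' @param delta Target fraction of differing blocks, in \[0, 1\].
#' @param block_size Block granularity in bytes.
#' @param n_files Number of files for [make_collection()].
#' @param seed Generator seed.
#' @return A `pfff_synthetic_spec`.
#' @export
synthetic_spec <- function(base_size, delta, block_size = 1L, n_files = 2L,
                           seed = 1L) {
  stopifnot(
    "base_size must be a positive integer" = base_size >= 1,
    "delta must lie in [0, 1]" = delta >= 0 && delta <= 1,
    "block_size must be >= 1" = block_size >= 1,
    "base_size must be at least block_size" = base_size >= block_size,
    "n_files must be >= 1" = n_files >= 1
  )
  structure(list(base_size = as.numeric(base_size), delta = delta,
                 block_size = as.numeric(block_size),
                 n_files = as.integer(n_files), seed = as.integer(seed)),
            class = "pfff_synthetic_spec")
}

random_bytes <- function(n) as.raw(sample.int(256L, n, replace = TRUE) - 1L)

#' Generate a file pair with an exact number of differing blocks
#'
#' Writes a base file of seeded-random bytes and a variant differing in
#' exactly `d = ceiling(delta * block_count)` blocks chosen without
#' replacement.  Each altered block has its first byte incremented mod 256
#' (guaranteeing a byte difference without rejection sampling) and the rest
#' of the block re-randomized.  Byte-identical output for equal spec + seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created; default a fresh temporary
#'   directory).
#' @return A list with `file_a`, `file_b`, `d` (differing block count),
#'   `block_count`, `dir` and `spec`.  [pairwise_delta()] on the pair at the
#'   spec's block size returns exactly `d / block_count`.
#' @export
#' @examples
#' p <- make_pair(synthetic_spec(1000, delta = 0.37))
#' pairwise_delta(p$file_a, p$file_b)$delta  # 0.37
make_pair <- function(spec, dir = tempfile("pfff_pair_")) {
  stopifnot(inherits(spec, "pfff_synthetic_spec"))
  block_count <- ceiling(spec$base_size / spec$block_size)
  if (spec$delta > 0 && block_count == 0)
    stop("delta > 0 requires at least one block")
  d <- ceiling(spec$delta * block_count)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file_a <- file.path(dir, "base.bin")
  file_b <- file.path(dir, "variant.bin")
  with_local_seed(spec$seed, {
    base <- random_bytes(spec$base_size)
    variant <- base
    if (d > 0) {
      altered <- sort(sample.int(block_count, d))
      for (blk in altered) {
        start <- (blk - 1) * spec$block_size + 1
        end <- min(blk * spec$block_size, spec$base_size)
        variant[start] <- as.raw((as.integer(base[start]) + 1L) %% 256L)
        if (end > start)
          variant[(start + 1):end] <- random_bytes(end - start)
      }
    }
    writeBin(base, file_a)
    writeBin(variant, file_b)
  })
  list(file_a = file_a, file_b = file_b, d = d, block_count = block_count,
       dir = dir, spec = spec)
}

#' Monte-Carlo check of the sampling-collision probability
#'
#' Generates one pair with exactly `d` of `block_count` blocks differing and
#' draws the sampled block positions under `n_keys` distinct keys (the same
#' pseudorandom stream [pfff_fingerprint()] uses).  A key yields a sampling
#' collision when the two sample vectors are byte-identical, i.e. no sampled
#' position lands on a differing block.  Reports the empirical collision
#' rate next to the exact closed form `((block_count - d) / block_count) ^
#' samples` for with-replacement sampling and the variability bound
#' `(1 - delta)^samples`.
#'
#' @param spec A [synthetic_spec()].
#' @param samples Sample count per fingerprint.
#' @param n_keys Number of distinct keys (at least 100).
#' @param key_seed Seed for drawing the keys (independent of the content
#'   stream).
#' @return A list with `empirical`, `analytic`, `bound`, `collisions`,
#'   `n_keys`, `d`, `block_count`.
#' @export
collision_experiment <- function(spec, samples, n_keys = 1e5, key_seed = 1L) {
  stopifnot(inherits(spec, "pfff_synthetic_spec"),
            "n_keys must be at least 100" = n_keys >= 100,
            "samples must be >= 1" = samples >= 1)
  pair <- make_pair(spec)
  on.exit(unlink(pair$dir, recursive = TRUE), add = TRUE)
  a <- readBin(pair$file_a, "raw", spec$base_size)
  b <- readBin(pair$file_b, "raw", spec$base_size)
  bs <- spec$block_size
  diff_byte <- which(a != b)
  is_diff <- logical(pair$block_count)
  is_diff[unique((diff_byte - 1) %/% bs) + 1] <- TRUE
  keys <- with_local_seed(key_seed,
    sample.int(.Machine$integer.max, n_keys, replace = FALSE))
  collisions <- cpp_sampling_collision_count(
    as.numeric(keys), pair$block_count, as.integer(samples), is_diff,
    skip = 1L)
  list(empirical = collisions / n_keys,
       analytic = ((pair$block_count - pair$d) / pair$block_count)^samples,
       bound = (1 - spec$delta)^samples,
       collisions = collisions, n_keys = n_keys,
       d = pair$d, block_count = pair$block_count)
}

#' Generate a collection with planted duplicates
#'
#' Writes `n_files` independent random-byte files (pairwise variability
#' close to 255/256 with overwhelming probability, hence at least the spec's
#' `delta` for any realistic choice) plus exact copies of the first
#' `planted_duplicates` files, and a JSON manifest recording sizes and the
#' planted duplicate sets — the ground truth for duplicate-detection tests.
#'
#' @param spec A [synthetic_spec()] (uses `n_files`, `base_size`, `seed`).
#' @param planted_duplicates Number of files to duplicate exactly (0 to
#'   `n_files`).
#' @param dir Output directory.
#' @return A list with `dir`, `files` (all paths, duplicates included),
#'   `duplicate_sets` (list of character vectors), and `manifest` (path to
#'   the JSON manifest).
#' @export
make_collection <- function(spec, planted_duplicates = 0L,
                            dir = tempfile("pfff_coll_")) {
  stopifnot(inherits(spec, "pfff_synthetic_spec"),
            "need n_files >= 2" = spec$n_files >= 2,
            planted_duplicates >= 0, planted_duplicates <= spec$n_files)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  names <- sprintf("file_%03d.bin", seq_len(spec$n_files))
  paths <- file.path(dir, names)
  with_local_seed(spec$seed, {
    for (p in paths) writeBin(random_bytes(spec$base_size), p)
  })
  dup_sets <- list()
  if (planted_duplicates > 0) {
    for (i in seq_len(planted_duplicates)) {
      dup <- file.path(dir, sprintf("dup_of_%03d.bin", i))
      file.copy(paths[i], dup)
      dup_sets[[i]] <- c(basename(paths[i]), basename(dup))
      paths <- c(paths, dup)
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(spec = unclass(spec), files = basename(paths),
         sizes = rep(spec$base_size, length(paths)),
         duplicate_sets = dup_sets),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  list(dir = dir, files = paths, duplicate_sets = dup_sets,
       manifest = manifest)
}
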