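---
title: "Sampled file fingerprinting: model, guarantees, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampled file fingerprinting: model, guarantees, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfff)
```

## The problem

Comparing or synchronizing large scientific data files usually means hashing
them, and hashing means reading every byte. For terabyte-scale collections —
sequencing runs, microarray warehouses, genome annotation mirrors — the full
scan is the bottleneck, and it is paid again for every remote mirror that
wants to check whether its copy is current. `pfff` replaces the full scan
with a keyed fingerprint over a *pseudorandom sample* of blocks, so the work
per file is a constant number of reads (and, over HTTP, a constant number of
range requests) regardless of file size.

## Model and guarantees

Treat a file of `m` bytes as `ceiling(m / B)` aligned blocks of `B` bytes
(the last block may be short; the default granularity is `B = 1`, single
bytes). The **δ-variability assumption** says that in the collection at
hand, any two meaningfully distinct files of equal length differ in at least
a δ fraction of their blocks. This is an empirical property of scientific
data: measurements are noisy, no two experiments agree byte-for-byte, and
compression spreads any difference across the stream. Surveys of public
genomics repositories put δ above 0.2 for most uncompressed datasets and
above 0.9 for gzip-compressed ones; the exceptions are re-packagings of the
same underlying data, or uncompressed genome builds differing only in a
small patched region.

Sampling ℓ positions uniformly with replacement, two files satisfying the
assumption collide on all sampled blocks with probability at most
`(1 − δ)^ℓ` (`sampling_collision_bound()`); a union bound over the
`n(n−1)/2` pairs of an `n`-file collection gives the collection-wide bound
(`collection_collision_bound()`), and inverting it yields the sample count

```
ℓ ≥ (log(1/ε_fail) + 2 log n) / (−log(1 − δ))
```

(`required_sample_size()`). The count is independent of file size and
logarithmic in both the budget and the collection size:

```{r}
required_sample_size(2^-64, 1e6, 0.9)
required_sample_size(2^-64, 1e6, 0.2)
required_sample_size(0.05, 59892, 0.9)
```

The sampled blocks are not compared directly; they are compressed by a keyed
ε_c-almost-universal family, which adds at most ε_c ≈ `ceiling(L/7)/(2^61−1)`
(message length `L`) to the per-pair collision probability — negligible next
to ε_s for any practical ℓ.

## The fingerprint format (this implementation's dialect)

The mathematical scheme leaves the concrete format open: the hash family,
the key width, how indices are derived, and how the message is serialized.
These are fixed here as follows, and they *are* the format — two parties get
comparable digests exactly when their canonical config strings
(`config_string()`) agree.

* **Key and pseudorandomness.** The key is a single unsigned 64-bit word
  seeding a 64-bit Mersenne twister. One stream, fixed draw order: the first
  output word is reserved for compression key material, the following words
  become the ℓ block indices (successive outputs reduced modulo the block
  count; `generate_indices()` exposes the raw stream via its `skip`
  argument). Modulo reduction carries a bias of order `block_count / 2^64`,
  accepted as negligible — any sufficiently good generator serves, and the
  twister is fast and ubiquitous. The default key is a fixed published
  constant (`pfff_default_key()`), so independent parties agree by default;
  any other key must be shared out of band.
* **Message assembly.** Size field (8-byte little-endian, on by default), then
  the first `header_bytes` of the file (off by default), then the ℓ sampled
  blocks in generation order. Sampling is with replacement, duplicates and
  all. Spans may be *read* in ascending offset order (and are coalesced into
  batched range requests over HTTP) but are always *assembled* in generation
  order.
* **Short-file path.** When `m ≤ ℓ·B` the whole content is hashed instead of
  samples. Reading everything is strictly cheaper than sampling would be,
  collisions are then bounded by ε_c alone, and the rule is a deterministic
  function of the sizes, so both sides of any comparison take the same path.
* **Compression.** Default family `poly61`: the message is split into 7-byte
  little-endian chunks `c_0 … c_{t−1}` (last chunk zero-padded) and the
  polynomial `Σ c_j r^{t−j} + t` is evaluated modulo the Mersenne prime
  `2^61 − 1`, at the point `r ∈ [2, p−2]` derived from the key's reserved
  twister word. Two fixed messages of at most `L` bytes collide over a
  random key with probability at most `ceiling(L/7)/(2^61−1)` — a *provable*
  bound, which is why this family is the default. The 61-bit result is
  widened to 64 or 128 bits by a fixed bijective finalization mix (bijective,
  so it neither creates nor destroys collisions). The `crypto` family
  (truncated SHA-256 of key-then-message) is offered for interoperability
  habit; its ε_c is the usual heuristic `2^−digest_bits`.
* **Size inclusion.** The variability assumption speaks only about
  equal-length files, so the size field is on by default: different-length
  files then never collide, closing the one gap the assumption leaves. The
  header option (a megabyte is a reasonable value) hardens the digest
  further, since most formats concentrate identifying information in the
  header.
* **Rendering.** Lowercase hex, fixed width `digest_bits/4`; digest lines are
  `"<hexdigest>  <path-or-url>"`, checksum-tool style.

## The δ estimators

`pairwise_delta()` computes the statistic exactly by streaming both files in
bounded memory. Files of unequal length are compared over their common
prefix with both sizes reported — the variability statistic is strictly
positional, so this is a declared convention rather than a claim about
insertions (an insertion shifts everything after it and drives δ toward 1;
alignment-aware similarity is out of scope). `estimate_delta()` samples
block positions with replacement and attaches an exact Clopper–Pearson 95%
interval; 2000 probes give a CI half-width of about 0.022 at δ = 0.5, which
is ample for deciding between the δ = 0.2 and δ = 0.9 operating points.
`collection_min_delta()` ranks all pairs (content-driven, never name-driven,
so misnamed copies are found) and, in sampled mode, confirms the most
similar candidates exactly — the top pair's δ is the collection's
variability in the survey sense.

## Duplicate detection as a hypothesis test

`plan_test()` turns the bound around: fix a significance level (0.05 by
convention), postulate δ, and size ℓ so that under the null hypothesis —
*all files in the warehouse satisfy δ-variability* — the probability of any
digest collision is below the level. Every collision group reported by
`find_duplicates()` is then evidence rejecting the null: the members are
identical or suspiciously similar. Because the size field is inside the
digest, groups can never span different file sizes. `confirm = TRUE`
separates the two readings of a group by full-content comparison, splitting
"equal or equivalent" into byte-identical classes; unreadable files degrade
to warnings so a long warehouse scan is never aborted by one bad member.

## What the synthetic generator emulates — and what it does not

`make_pair()` constructs pairs with an *exactly* controlled number of
differing blocks (`d = ceiling(δ · block_count)`; each altered block has its
first byte incremented mod 256 — a guaranteed difference without rejection
loops — and the rest re-randomized). `make_collection()` adds independent
random files (pairwise δ ≈ 255/256 at byte granularity, far above any
operating point) plus planted exact duplicates recorded in a JSON manifest.
The generator's stream is seeded separately from the fingerprint keys, so
collision experiments over keys run against fixed content.

This gives exact ground truth for the quantities the theory speaks about:
`collision_experiment()` measures the empirical sampling-collision rate over
many keys against the closed form `((block_count − d)/block_count)^ℓ` and
the bound `(1 − δ)^ℓ`, and the test suite checks the planner's false-alarm
budget on 100-file collections, estimator coverage, and exhaustive
enumeration of all index tuples at small sizes. What synthetic collections
do *not* emulate: real formats' internal structure (headers, repeated
magic bytes, long runs), correlated similarity between related experiments,
or compression artifacts. Passing these tests therefore validates the
*mathematics and the implementation*, not the δ-variability of any
particular real collection — that must be checked per collection with the δ
estimators, which is exactly what they are for.

## Numerical and engineering choices

* Sample sizes use `log1p(-delta)` for accuracy at small δ, and the minimal
  integer is the plain ceiling of the double-precision bound; the published
  operating points sit far from integer knife-edges.
* `(1 − δ)^ℓ` at δ = 0.5 is exact in binary floating point (a power of two),
  so the worked bound 2⁻¹⁰³ is reproduced bit-for-bit.
* The 64-bit twister and the GF(2⁶¹−1) arithmetic live in C++ (R has no
  native unsigned 64-bit integers); keys outside the exact-double range are
  passed as decimal or hex strings. Multiplication mod the Mersenne prime
  uses 128-bit intermediates with the standard fold.
* HTTP sources require a `Content-Length` up front (the sample count depends
  on the size); servers without one, or servers ignoring `Range`, are an
  explicit failure under the `require` policy and a one-time full download
  under `fallback-full`. Batched reads try a single multi-range request
  first and parse `multipart/byteranges`; a `200` full-body answer falls
  back to per-span requests. Retries are a single configurable count — this
  is a desk tool, not a transfer manager.
* Degenerate inputs are defined, not accidental: an empty file fingerprints
  to the compressed size field; δ between empty files is reported as
  undefined with an explicit flag; a single-block file yields all-zero
  indices.

## Validation problem sizes

The shipped tests validate the guarantees at sizes chosen to make the
binomial statistics sharp while keeping the suite quick on a single CPU:
10⁵ keys for Monte-Carlo collision rates (99% binomial intervals around the
closed form), 40 seeded 100-file collections for the false-alarm budget,
a 51-file suite (empty through multi-kilobyte) for determinism and
local-versus-HTTP equivalence against an in-process fixture server, 10⁶
twister draws for the uniformity goodness-of-fit, and 100 seeded trials for
estimator coverage. The analytic sizings (ℓ = 32, 11, 323) are exact
integer computations and are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* The guarantee is conditional on δ-variability; collections of uncompressed
  genome builds with small patched differences violate it, and there the
  honest answers are conventional hashing, compression (which restores
  variability), or a larger block size.
* Fingerprints are comparable only under identical configurations; there is
  no cross-config compatibility, and no compatibility with other tools'
  digest formats is claimed.
* The key is not a secret in the cryptographic sense: poly61 is
  almost-universal, not collision-resistant against an adversary who knows
  the key. For adversarial settings use the `crypto` family — or a real
  cryptographic hash over the full file.
* Remote fingerprinting inherits the server's honesty: a server that serves
  inconsistent ranges produces garbage digests. The `confirm` option of the
  duplicate detector is the corresponding safety net for local scans.
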