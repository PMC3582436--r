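#' Minimal sample count for a collision budget
#'
#' Under the delta-variability assumption (any two distinct same-length files
#' differ in at least a `delta` fraction of their blocks), sampling `l` block
#' positions with replacement bounds the probability that *some* pair among
#' `n_files` files collides by `0.5 * n * (n - 1) * (1 - delta)^l`.  This
#' function returns the smallest integer `l` satisfying
#'
#'   `l >= (log(1 / eps_fail) + 2 * log(n_files)) / (-log(1 - delta))`
#'
#' so that the collection-wide collision probability stays below `eps_fail`.
#' The required sample count does not depend on file size, and grows only
#' logarithmically in `1 / eps_fail` and `n_files`.
#'
#' @param eps_fail Collision budget for the whole collection, in (0, 1).
#' @param n_files Collection size (at least 2).
#' @param delta Variability: minimum fraction of differing blocks between
#'   meaningfully distinct same-length files, in (0, 1].  Empirically, 0.9 is
#'   a reasonable choice for collections of compressed files and 0.2 a safe
#'   general-purpose choice.
#' @return The minimal sample count, a positive integer.  `delta = 1` gives 1
#'   (a single sampled block suffices when every block differs).
#' @seealso [sampling_collision_bound()], [collection_collision_bound()],
#'   [plan_test()]
#' @export
#' @examples
#' required_sample_size(2^-64, 1e6, 0.9)   # 32
#' required_sample_size(0.05, 59892, 0.9)  # 11
#' required_sample_size(2^-64, 1e6, 0.2)   # 323
required_sample_size <- function(eps_fail, n_files, delta) {
  stopifnot(
    "eps_fail must be a probability strictly between 0 and 1" =
      is.numeric(eps_fail) && length(eps_fail) == 1 && eps_fail > 0 &&
      eps_fail < 1,
    "n_files must be a single integer >= 2" =
      is.numeric(n_files) && length(n_files) == 1 && n_files >= 2,
    "delta must lie in (0, 1]; delta = 0 makes the variability assumption vacuous" =
      is.numeric(delta) && length(delta) == 1 && delta > 0 && delta <= 1
  )
  if (delta == 1) return(1L)
  # log1p keeps -log(1 - delta) accurate for small delta
  bound <- (-log(eps_fail) + 2 * log(n_files)) / (-log1p(-delta))
  max(1L, as.integer(ceiling(bound)))
}

#' Sampling-collision probability bound for one pair
#'
#' If two distinct same-length files differ in at least a `delta` fraction of
#' their blocks, the probability that `samples` positions drawn uniformly
#' with replacement all land on coinciding blocks (a *sampling collision*) is
#' at most `(1 - delta)^samples`.
#'
#' @param delta Variability fraction, in \[0, 1\].
#' @param samples Number of sampled blocks (non-negative; 0 gives 1 — an
#'   empty sample distinguishes nothing).
#' @return The bound `(1 - delta)^samples`.
#' @export
#' @examples
#' sampling_collision_bound(0.5, 103)  # 2^-103
sampling_collision_bound <- function(delta, samples) {
  stopifnot(
    "delta must lie in [0, 1]" =
      is.numeric(delta) && length(delta) == 1 && delta >= 0 && delta <= 1,
    "samples must be a single non-negative integer" =
      is.numeric(samples) && length(samples) == 1 && samples >= 0 &&
      samples == floor(samples)
  )
  (1 - delta)^samples
}

#' Any-collision probability bound over a collection
#'
#' Union bound over all unordered pairs: with per-pair sampling-collision
#' probability at most `eps_s`, some collision among `n_files` files occurs
#' with probability at most `0.5 * n * (n - 1) * eps_s` (clamped to 1).
#'
#' @param n_files Collection size (at least 1).
#' @param eps_s Per-pair sampling-collision probability, in \[0, 1\].
#' @return The bound, clamped to \[0, 1\].
#' @export
#' @examples
#' collection_collision_bound(1e6, 2^-103)  # ~4.93e-20
collection_collision_bound <- function(n_files, eps_s) {
  stopifnot(
    "n_files must be a single integer >= 1" =
      is.numeric(n_files) && length(n_files) == 1 && n_files >= 1 &&
      n_files == floor(n_files),
    "eps_s must lie in [0, 1]" =
      is.numeric(eps_s) && length(eps_s) == 1 && eps_s >= 0 && eps_s <= 1
  )
  min(1, 0.5 * n_files * (n_files - 1) * eps_s)
}

#' Collision parameter of the compression family
#'
#' For the `"poly61"` family (polynomial evaluation over GF(2^61 - 1) on
#' 7-byte chunks), any two fixed messages of at most `message_length` bytes
#' collide over a random key with probability at most
#' `ceiling(message_length / 7) / (2^61 - 1)`.  For the `"crypto"` family the
#' value is the heuristic `2^-digest_bits`.
#'
#' @param message_length Maximum message length in bytes.
#' @param family `"poly61"` or `"crypto"`.
#' @param digest_bits Digest width (used by `"crypto"` only).
#' @return The collision parameter, a small probability.
#' @export
#' @examples
#' eps_c_bound(1e6)
eps_c_bound <- function(message_length, family = c("poly61", "crypto"),
                        digest_bits = 64L) {
  family <- match.arg(family)
  stopifnot(
    "message_length must be a single non-negative number" =
      is.numeric(message_length) && length(message_length) == 1 &&
      message_length >= 0
  )
  if (family == "poly61") ceiling(message_length / 7) / (2^61 - 1)
  else 2^-digest_bits
}

#' All collision bounds for one parameterization
#'
#' Convenience calculator connecting the variability `delta`, the collection
#' size, the sample count and the compression family into the three collision
#' parameters: the per-pair sampling bound `eps_s`, the collection-wide bound
#' `eps_fail`, and the compression collision parameter `eps_c`.
#'
#' @inheritParams required_sample_size
#' @param samples Sample count; if `NULL`, the minimal count from
#'   [required_sample_size()] at `eps_fail_target`.
#' @param eps_fail_target Collision budget used to size `samples` when
#'   `samples` is `NULL` (default 2^-64).
#' @param message_length Message length for the `eps_c` calculation (default:
#'   the sampled volume, `samples` bytes per block of size 1 plus the 8-byte
#'   size field).
#' @param family Compression family, see [eps_c_bound()].
#' @return A one-row data frame with columns `delta`, `n_files`, `samples`,
#'   `eps_s`, `eps_fail`, `eps_c`.
#' @export
#' @examples
#' collision_bounds(0.9, 1e6)
collision_bounds <- function(delta, n_files, samples = NULL,
                             eps_fail_target = 2^-64,
                             message_length = NULL,
                             family = c("poly61", "crypto")) {
  family <- match.arg(family)
  if (is.null(samples))
    samples <- required_sample_size(eps_fail_target, n_files, delta)
  eps_s <- sampling_collision_bound(delta, samples)
  eps_fail <- collection_collision_bound(n_files, eps_s)
  if (is.null(message_length)) message_length <- samples + 8
  data.frame(delta = delta, n_files = n_files, samples = samples,
             eps_s = eps_s, eps_fail = eps_fail,
             eps_c = eps_c_bound(message_length, family))
}
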