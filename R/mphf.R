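# BBHash-style minimal perfect hash over the vertex set.

#' Build a minimal perfect hash function over a set of k-mers
#'
#' Multi-level collision-free bit marking: at each level every surviving key
#' is hashed into a codomain of `ceiling(gamma * n_level)` bits; positions
#' hit exactly once are set in that level's bit array and resolve their key,
#' colliding keys move on to the next level. Keys still unresolved after
#' `max_levels` go to an exact fallback map (sorted packed keys, binary
#' search). The final hash of a key resolved at level i is the rank of its
#' set bit within the concatenated bit arrays, so the image is exactly
#' `[0, n)`.
#'
#' `gamma` trades encoding size for speed: the bit arrays take an expected
#' `gamma * exp(1/gamma) * n` bits, and each key is probed an expected
#' `O(exp(1/gamma))` times. The default `gamma = 2` costs about 3.7 bits per
#' key including the rank index.
#'
#' @param keys a `vertex_spectrum` or a character vector of distinct
#'   equal-length k-mers.
#' @param gamma codomain expansion factor, > 0.
#' @param seed integer seed for the level hash functions.
#' @param max_levels maximum number of bit-array levels before falling back
#'   to the exact map.
#' @return an object of class `mphf`.
#' @examples
#' h <- build_mphf(c("ACG", "CGT", "AAA"), seed = 1)
#' sort(mphf_query(h, c("ACG", "CGT", "AAA"))) # 0 1 2
#' @export
build_mphf <- function(keys, gamma = 2, seed = 1L, max_levels = 25L) {
  if (inherits(keys, "vertex_spectrum")) keys <- keys$mer
  stopifnot(is.character(keys), length(keys) >= 1L)
  k <- nchar(keys[1L])
  if (!all(nchar(keys) == k)) stop("all keys must have equal length")
  if (gamma <= 0) stop("gamma must be > 0")
  ptr <- cpp_mphf_build(keys, as.numeric(gamma), as.numeric(seed),
                        as.integer(max_levels), as.integer(k))
  structure(list(ptr = ptr, n = length(keys), k = k, gamma = gamma,
                 seed = as.integer(seed)),
            class = "mphf")
}

#' Query a minimal perfect hash
#'
#' Deterministic; over the build key set the values are a bijection onto
#' `[0, n)`. Keys outside the build set return an arbitrary value in
#' `[0, n)` (the pipeline never presents such keys: the vertex set is
#' derived from the very edges that are later traversed).
#'
#' @param h an `mphf`.
#' @param keys character vector of k-mers.
#' @return numeric vector of hash values in `[0, n)`.
#' @export
mphf_query <- function(h, keys) {
  stopifnot(inherits(h, "mphf"))
  if (inherits(keys, "vertex_spectrum")) keys <- keys$mer
  cpp_mphf_query(h$ptr, keys)
}

#' Number of hash levels probed per key
#'
#' The expected number of probes decays as `exp(1/gamma)`; larger `gamma`
#' means fewer levels touched per query.
#'
#' @inheritParams mphf_query
#' @return integer vector of per-key level counts.
#' @export
mphf_probe_levels <- function(h, keys) {
  stopifnot(inherits(h, "mphf"))
  if (inherits(keys, "vertex_spectrum")) keys <- keys$mer
  cpp_mphf_probe_levels(h$ptr, keys)
}

#' Total encoding size of a minimal perfect hash
#'
#' Bits of all level bit arrays, plus the rank index (one 64-bit cumulative
#' count per 512-bit block), plus the fallback map and per-level metadata.
#' Transient build-time collision arrays are excluded.
#'
#' @param h an `mphf`.
#' @return size in bits.
#' @export
mphf_size_bits <- function(h) {
  stopifnot(inherits(h, "mphf"))
  cpp_mphf_info(h$ptr)$size_bits
}

#' Structural details of a minimal perfect hash
#' @param h an `mphf`.
#' @return a list: `n`, `k`, `gamma`, `seed`, `n_levels`, per-level codomain
#'   sizes, fallback count, and the size accounting in bits.
#' @export
mphf_info <- function(h) {
  stopifnot(inherits(h, "mphf"))
  cpp_mphf_info(h$ptr)
}

#' Serialize / restore a minimal perfect hash
#'
#' Versioned little-endian binary dump of the level bit arrays, seeds and
#' fallback map, so a build can be reused across pipeline stages and runs.
#'
#' @param h an `mphf`.
#' @param path file path.
#' @return `mphf_save` returns `path` invisibly; `mphf_load` returns the
#'   restored `mphf`.
#' @export
mphf_save <- function(h, path) {
  stopifnot(inherits(h, "mphf"))
  cpp_mphf_save(h$ptr, path)
  invisible(path)
}

#' @rdname mphf_save
#' @export
mphf_load <- function(path) {
  ptr <- cpp_mphf_load(path)
  info <- cpp_mphf_info(ptr)
  structure(list(ptr = ptr, n = info$n, k = info$k, gamma = info$gamma,
                 seed = as.integer(info$seed)),
            class = "mphf")
}

#' @export
print.mphf <- function(x, ...) {
  info <- cpp_mphf_info(x$ptr)
  cat("<mphf> n =", format(x$n, big.mark = ","), " k =", x$k,
      " gamma =", x$gamma, "\n")
  cat("  levels:", info$n_levels, " fallback keys:", info$n_fallback, "\n")
  cat(sprintf("  size: %.0f bits (%.2f bits/key)\n", info$size_bits,
              info$size_bits / max(1, x$n)))
  invisible(x)
}
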