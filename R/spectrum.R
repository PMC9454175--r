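# Edge spectrum (solid canonical (k+1)-mers) and vertex spectrum.

#' Signature of a window
#'
#' The signature used to partition (k+1)-mers into bins: the
#' lexicographically smallest canonical `msig`-mer window of the given
#' window. Invariant under reverse complement of the window, so a window and
#' its twin always land in the same bin.
#'
#' @param window a DNA string.
#' @param msig signature length, `msig <= nchar(window)`.
#' @return the signature string.
#' @examples
#' edge_signature("CTAA", 2) # "AA"
#' @export
edge_signature <- function(window, msig) {
  stopifnot(is.character(window), length(window) == 1L)
  cpp_signature(window, as.integer(msig))
}

#' Split a sequence into super l-mers
#'
#' Maximal substrings whose l-mer windows all share one signature, paired
#' with the bin each signature maps to. The per-substring l-mer streams
#' concatenate to the full valid l-mer stream of the sequence (windows
#' touching non-ACGT symbols are skipped).
#'
#' @param seq a sequence string.
#' @param l window length.
#' @param msig signature length (clamped to `l` when larger).
#' @param bins number of bins.
#' @return a data frame with columns `bin` (0-based) and `super_mer`.
#' @export
split_super_mers <- function(seq, l, msig = 9L, bins = 512L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  r <- cpp_split_super_mers(seq, as.integer(l), as.integer(msig),
                            as.integer(bins))
  data.frame(bin = r$bin, super_mer = r$super_mer, stringsAsFactors = FALSE)
}

#' Enumerate the edge set of the de Bruijn graph
#'
#' Counts all canonical (k+1)-mer occurrences of the input sequences (a
#' window and its reverse complement pool into one counter) via
#' signature-partitioned sort-and-count, and keeps those with total
#' abundance at least `f0` (the solid edges). `k` must be odd, so a k-mer is
#' never its own reverse complement; palindromic (k+1)-mers are stored once
#' with all their occurrences pooled.
#'
#' @param seqs character vector of DNA sequences (reads or references).
#' @param k odd k-mer length, `3 <= k <= 127`.
#' @param f0 solidity threshold (>= 1); (k+1)-mers seen fewer times are
#'   treated as sequencing errors and discarded.
#' @param msig,bins signature length and bin count of the partition scheme.
#' @param memory_budget approximate in-memory byte budget for bin buffers;
#'   above it, buffers spill to temporary files under `work_dir`.
#' @param work_dir directory for temporary bin files (deleted on success).
#' @return an object of class `edge_spectrum`: `k`, `f0`, sorted `mer`
#'   (canonical (k+1)-mers), `count`, and `m = length(mer)`.
#' @examples
#' enumerate_edges(c("CTAAGAT", "CGATGCA", "TAAGAGG"), k = 3, f0 = 1)
#' @export
enumerate_edges <- function(seqs, k, f0 = 1L, msig = 9L, bins = 512L,
                            memory_budget = 256 * 1024^2,
                            work_dir = tempdir()) {
  k <- as.integer(k)
  f0 <- as.integer(f0)
  if (is.na(k) || k <= 0L || k %% 2L == 0L)
    stop("k must be a positive odd integer")
  if (k > 127L) stop("k must be <= 127")
  if (is.na(f0) || f0 < 1L) stop("f0 must be >= 1")
  seqs <- as.character(seqs)
  r <- cpp_enumerate_edges(seqs, k, f0, as.integer(msig), as.integer(bins),
                           as.numeric(memory_budget), work_dir)
  structure(list(k = k, f0 = f0, mer = r$mer, count = r$count,
                 m = length(r$mer)),
            class = "edge_spectrum")
}

#' @export
print.edge_spectrum <- function(x, ...) {
  cat("<edge_spectrum> k =", x$k, " f0 =", x$f0, " m =", x$m,
      "canonical (k+1)-mers\n")
  if (x$m > 0L) {
    show <- head(seq_len(x$m), 6L)
    cat(paste0("  ", x$mer[show], " x", x$count[show]), sep = "\n")
    if (x$m > 6L) cat("  ...\n")
  }
  invisible(x)
}

#' Extract the vertex set from an edge spectrum
#'
#' The distinct canonical k-mers occurring as the prefix or suffix k-mer of
#' any edge, sorted.
#'
#' @param es an `edge_spectrum`.
#' @return an object of class `vertex_spectrum`: `k`, sorted `mer`, and
#'   `n = length(mer)`.
#' @export
extract_vertices <- function(es) {
  stopifnot(inherits(es, "edge_spectrum"))
  v <- cpp_extract_vertices(es$mer, es$k)
  structure(list(k = es$k, mer = v, n = length(v)),
            class = "vertex_spectrum")
}

#' @export
print.vertex_spectrum <- function(x, ...) {
  cat("<vertex_spectrum> k =", x$k, " n =", x$n, "canonical k-mers\n")
  invisible(x)
}
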