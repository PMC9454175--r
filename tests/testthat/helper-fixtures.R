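# Shared fixtures and small checkers for the suite.

# The running example: three short sequences whose k=3 graph has 10 vertices,
# 10 edges (one a palindromic loop), four maximal unitigs and exactly two
# maximal path covers.
worked_example <- function() c("CTAAGAT", "CGATGCA", "TAAGAGG")

rand_mers <- function(n, j, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), j, replace = TRUE), collapse = ""),
    character(1))
}

distinct_canonical_mers <- function(n, j, seed) {
  out <- character(0)
  s <- seed
  while (length(out) < n) {
    out <- unique(c(out, canonical_mer(rand_mers(n + 1000, j, s))$mer))
    s <- s + 1
  }
  out[seq_len(n)]
}

# canonical k-mer multiset of a set of records (cycles contribute their
# n vertices like paths do: the spelling holds each exactly once)
spelled_kmers <- function(spellings, k) {
  out <- unlist(lapply(spellings, function(s) {
    w <- valid_jmers(s, k)$mer
    canonical_mer(w)$mer
  }), use.names = FALSE)
  if (is.null(out)) character(0) else out
}

# every consecutive (k+1)-mer of every record is a solid edge (cyclic
# records also check the wrap window)
all_edges_solid <- function(records, es) {
  k <- es$k
  for (i in seq_len(nrow(records))) {
    s <- records$spelling[i]
    full <- if (records$is_cycle[i]) paste0(s, substr(s, k, k)) else s
    w <- valid_jmers(full, k + 1)$mer
    if (!all(canonical_mer(w)$mer %in% es$mer)) return(FALSE)
  }
  TRUE
}
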