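# Synthetic inputs: uniform random genomes and substitution-error reads.

#' Generate a uniform random genome
#'
#' @param length genome length in bases.
#' @param seed integer seed; fixed seed gives identical output.
#' @return a single DNA string.
#' @export
random_genome <- function(length, seed = 1L) {
  set.seed(as.integer(seed))
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Simulate shotgun reads from a genome
#'
#' Reads are sampled uniformly from both strands, with independent per-base
#' substitution errors at `error_rate`. Substitution only: the graph
#' algorithms see the input exclusively through its (k+1)-mer spectrum,
#' which substitutions already perturb. Read start positions may overhang
#' the genome ends (overhanging reads are clipped), so terminal windows
#' receive the same expected coverage as interior ones -- without this, the
#' first and last (k+1)-mers would almost never reach a solidity threshold
#' regardless of nominal coverage. Deterministic under `seed`.
#'
#' @param genome a DNA string.
#' @param read_len read length (clamped to the genome length); clipped
#'   terminal reads may be shorter.
#' @param coverage target mean coverage; the number of reads is
#'   `ceiling(coverage * genome_length / read_len)`.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a named character vector of reads.
#' @export
simulate_reads <- function(genome, read_len = 100L, coverage = 30,
                           error_rate = 0, seed = 1L) {
  L <- nchar(genome)
  read_len <- min(as.integer(read_len), L)
  n <- as.integer(ceiling(coverage * L / read_len))
  set.seed(as.integer(seed))
  starts <- sample.int(L + read_len - 1L, n, replace = TRUE) - read_len + 1L
  ends <- pmin(starts + read_len - 1L, L)
  starts <- pmax(starts, 1L)
  reads <- substring(genome, starts, ends)
  flip <- runif(n) < 0.5
  reads[flip] <- .rc(reads[flip])
  if (error_rate > 0) {
    sp <- strsplit(reads, "")
    lens <- lengths(sp)
    chars <- unlist(sp)
    hit <- which(runif(length(chars)) < error_rate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      reads <- vapply(split(chars, rep(seq_along(lens), lens)), paste,
                      character(1), collapse = "")
    }
  }
  names(reads) <- paste0("read_", seq_len(n))
  reads
}
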