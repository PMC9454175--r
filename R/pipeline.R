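# The five-stage pipeline: edges -> vertices -> hash -> states -> unitigs.

#' Construct the compacted de Bruijn graph (or a maximal path cover)
#'
#' Runs the full pipeline on reads or reference sequences: enumerate the
#' solid canonical (k+1)-mers (edges), extract the distinct canonical
#' k-mers (vertices), build a minimal perfect hash over the vertices, fold
#' the edges into per-vertex automaton states, and stitch the maximal
#' unitigs together. In `"path-cover"` mode the state computation admits
#' each edge only when both of its endpoint sides are still free, yielding
#' a maximal vertex-disjoint path cover instead of the unitigs.
#'
#' @param input character vector: paths to FASTA/FASTQ files (optionally
#'   gzipped), or raw sequence strings.
#' @param k odd k-mer length, `3 <= k <= 127`.
#' @param f0 solidity threshold: (k+1)-mers occurring fewer than `f0` times
#'   are discarded as sequencing errors.
#' @param mode `"unitigs"` or `"path-cover"`.
#' @param gamma minimal-perfect-hash trade-off parameter (> 0).
#' @param seed integer seed: drives the hash level seeds and, in path-cover
#'   mode, the edge admission order. Identical input and seed give
#'   byte-identical output.
#' @param msig,bins signature length and bin count for edge counting.
#' @param memory_budget in-memory byte budget for counting buffers.
#' @param work_dir scratch directory for counting spill files.
#' @param verbose log per-stage counts and timings to stderr.
#' @return an object of class `cdbg`: the `unitigs` data frame
#'   (`spelling`, `vertex_count`, `is_cycle`), the run parameters, and
#'   `stats` (m edges, n vertices, record and length totals).
#' @examples
#' res <- compact_dbg(c("CTAAGAT", "CGATGCA", "TAAGAGG"), k = 3)
#' res$unitigs
#' @export
compact_dbg <- function(input, k, f0 = 1L, mode = c("unitigs", "path-cover"),
                        gamma = 2, seed = 1L, msig = 9L, bins = 512L,
                        memory_budget = 256 * 1024^2, work_dir = tempdir(),
                        verbose = FALSE) {
  mode <- match.arg(mode)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- local({
    last <- t0
    function() {
      now <- proc.time()[["elapsed"]]
      d <- now - last
      last <<- now
      d
    }
  })

  seqs <- if (length(input) > 0 && all(file.exists(input)))
    read_sequences(input)
  else as.character(input)
  say("read %d sequence(s), %.0f bp total [%.2fs]", length(seqs),
      sum(nchar(seqs)), tick())

  es <- enumerate_edges(seqs, k = k, f0 = f0, msig = msig, bins = bins,
                        memory_budget = memory_budget, work_dir = work_dir)
  say("edges: m = %d solid canonical (k+1)-mers [%.2fs]", es$m, tick())

  timings <- c(edges = NA_real_)
  if (es$m == 0L) {
    u <- data.frame(spelling = character(0), vertex_count = integer(0),
                    is_cycle = logical(0))
    class(u) <- c("unitig_set", "data.frame")
    attr(u, "k") <- es$k
    attr(u, "mode") <- mode
    return(structure(list(unitigs = u, k = es$k, f0 = es$f0, mode = mode,
                          gamma = gamma, seed = as.integer(seed),
                          stats = list(m = 0L, n = 0L, n_unitigs = 0L,
                                       total_length = 0L, n_cyclic = 0L)),
                     class = "cdbg"))
  }

  vs <- extract_vertices(es)
  say("vertices: n = %d distinct canonical k-mers [%.2fs]", vs$n, tick())

  h <- build_mphf(vs, gamma = gamma, seed = seed)
  say("hash: %d levels, %.2f bits/vertex [%.2fs]",
      mphf_info(h)$n_levels, mphf_size_bits(h) / vs$n, tick())

  st <- compute_states(es, h, mode = mode, order_seed = seed)
  say("states computed (%s mode) [%.2fs]", mode, tick())

  u <- extract_unitigs(vs, st, h)
  say("extracted %d records, %d bp cumulative [%.2fs]", nrow(u),
      sum(nchar(u$spelling)), tick())

  structure(list(
    unitigs = u, k = es$k, f0 = es$f0, mode = mode, gamma = gamma,
    seed = as.integer(seed),
    stats = list(m = es$m, n = vs$n, n_unitigs = nrow(u),
                 total_length = sum(nchar(u$spelling)),
                 n_cyclic = sum(u$is_cycle)),
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "cdbg")
}

#' @export
print.cdbg <- function(x, ...) {
  cat("<cdbg> k =", x$k, " f0 =", x$f0, " mode =", x$mode, "\n")
  cat("  edges m =", x$stats$m, " vertices n =", x$stats$n, "\n")
  cat("  records:", x$stats$n_unitigs,
      sprintf("(%d cyclic), cumulative length %d bp\n",
              x$stats$n_cyclic, x$stats$total_length))
  invisible(x)
}

#' @export
summary.cdbg <- function(object, ...) {
  print(object)
  if (object$stats$n_unitigs > 0L) {
    len <- nchar(object$unitigs$spelling)
    cat("  length range:", min(len), "-", max(len),
        " mean:", round(mean(len), 1), "\n")
  }
  invisible(object)
}
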