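# Standard-format input and output.

#' Read sequences from FASTA/FASTQ files
#'
#' The format of each file is auto-detected from its first record marker;
#' plain and gzip-compressed files are both accepted. FASTQ quality lines
#' are ignored.
#'
#' @param paths character vector of file paths.
#' @return a named character vector of sequences, in file order.
#' @export
read_sequences <- function(paths) {
  out <- character(0)
  for (p in paths) {
    if (!file.exists(p)) stop("input file not found: ", p)
    con <- gzfile(p, "rt")
    first <- tryCatch(readLines(con, n = 1L), finally = close(con))
    if (length(first) == 0L) next
    fmt <- if (startsWith(first, ">")) "fasta"
           else if (startsWith(first, "@")) "fastq"
           else stop("cannot detect FASTA/FASTQ format of ", p,
                     " (first line: ", substr(first, 1, 20), ")")
    x <- tryCatch(
      Biostrings::readDNAStringSet(p, format = fmt),
      error = function(e) stop("malformed ", fmt, " in ", p, ": ",
                               conditionMessage(e), call. = FALSE))
    s <- as.character(x)
    names(s) <- sub("\\s.*$", "", names(x))
    out <- c(out, s)
  }
  out
}

#' Write sequences to FASTA / FASTQ
#'
#' Small fixture-writing helpers. FASTQ qualities are constant `I`.
#'
#' @param seqs named character vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("read_", seq_along(seqs))
  lines <- as.vector(rbind(paste0("@", names(seqs)), unname(seqs), "+",
                           strrep("I", nchar(seqs))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write maximal unitigs to FASTA with a sidecar JSON report
#'
#' Records are written sorted by canonical spelling (deterministic output),
#' with headers `>u<i> LN:i:<length> KC:i:<vertex count> CY:i:<0|1>`. A
#' machine-readable run report (parameters, seed, counts) is written next
#' to the FASTA as `<path>.json`.
#'
#' @param x a `cdbg` result (from [compact_dbg()]) or a `unitig_set`.
#' @param path output FASTA path.
#' @param config optional named list merged into the report (used when `x`
#'   is a bare `unitig_set`).
#' @return `path`, invisibly.
#' @export
write_unitigs <- function(x, path, config = list()) {
  if (inherits(x, "cdbg")) {
    u <- x$unitigs
    report <- c(list(k = x$k, f0 = x$f0, mode = x$mode, gamma = x$gamma,
                     seed = x$seed, version = as.character(
                       utils::packageVersion("cdbg"))),
                x$stats)
  } else {
    u <- x
    report <- c(config, list(
      n = sum(u$vertex_count), n_unitigs = nrow(u),
      total_length = sum(nchar(u$spelling))))
  }
  stopifnot(is.data.frame(u))
  hdr <- sprintf("u%d LN:i:%d KC:i:%d CY:i:%d", seq_len(nrow(u)),
                 nchar(u$spelling), u$vertex_count, as.integer(u$is_cycle))
  s <- u$spelling
  names(s) <- hdr
  if (nrow(u) == 0L) {
    writeLines(character(0), path)  # empty FASTA
  } else {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(s), path)
  }
  jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
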