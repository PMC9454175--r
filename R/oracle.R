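# Brute-force reference implementations. Intentionally naive: plain
# dictionaries and explicit adjacency, no code shared with the packed /
# hashed pipeline. These define ground truth for the test suite.

.rc <- function(x) stringi::stri_reverse(chartr("ACGT", "TGCA", x))
.canon <- function(x) {
  if (!length(x)) return(character(0))
  r <- .rc(x)
  ifelse(x <= r, x, r)
}
.comp1 <- function(c) chartr("ACGT", "TGCA", c)

# valid j-windows of one sequence (non-ACGT splits, case-insensitive)
.windows <- function(seq, j) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < j) return(character(0))
  w <- substring(seq, 1:(n - j + 1), j:n)
  w[grepl("^[ACGT]+$", w)]
}

#' Dictionary count of canonical (k+1)-mers
#'
#' The naive counter: every valid (k+1)-mer window of every sequence,
#' pooled with its reverse complement under the canonical form.
#'
#' @param seqs character vector of sequences.
#' @param k k-mer length.
#' @return a data frame with columns `mer` (sorted) and `count`.
#' @export
oracle_edge_counts <- function(seqs, k) {
  occ <- .canon(unlist(lapply(seqs, .windows, j = k + 1L), use.names = FALSE))
  if (length(occ) == 0L)
    return(data.frame(mer = character(0), count = integer(0)))
  occ <- sort(occ)
  r <- rle(occ)
  data.frame(mer = r$values, count = r$lengths, stringsAsFactors = FALSE)
}

# incidences of canonical edges per the side rules: an edge exits through
# its prefix k-mer's back iff the prefix is canonical; enters through its
# suffix k-mer's front iff the suffix is canonical. Vectorized; returns two
# rows per edge (the u-incidence, then the v-incidence).
.incidences_vec <- function(edges, k) {
  u <- substr(edges, 1L, k)
  v <- substr(edges, 2L, k + 1L)
  ur <- .rc(u); vr <- .rc(v)
  ucan <- u <= ur; vcan <- v <= vr
  last <- substr(edges, k + 1L, k + 1L)
  first <- substr(edges, 1L, 1L)
  m <- length(edges)
  idx <- rep(seq_len(m), each = 2L)
  vertex <- character(2L * m)
  side <- character(2L * m)
  symbol <- character(2L * m)
  odd <- seq(1L, 2L * m, by = 2L)
  vertex[odd] <- ifelse(ucan, u, ur)
  vertex[odd + 1L] <- ifelse(vcan, v, vr)
  side[odd] <- ifelse(ucan, "back", "front")
  side[odd + 1L] <- ifelse(vcan, "front", "back")
  symbol[odd] <- ifelse(ucan, last, .comp1(last))
  symbol[odd + 1L] <- ifelse(vcan, first, .comp1(first))
  data.frame(edge = edges[idx], vertex = vertex, side = side,
             symbol = symbol, stringsAsFactors = FALSE)
}

.incidences <- function(edge, k) .incidences_vec(edge, k)

#' Materialize the bidirected de Bruijn graph explicitly
#'
#' Dictionary-counts the canonical (k+1)-mers of the input, keeps those with
#' abundance at least `f0` as edges, derives the vertices, and records every
#' per-vertex per-side incidence with the symbol that encodes the edge at
#' that side. A loop edge incident twice to the same side with the same
#' symbol (a palindromic edge) yields a single incidence.
#'
#' @param seqs character vector of sequences.
#' @param k odd k-mer length.
#' @param f0 solidity threshold.
#' @return an object of class `explicit_dbg`: `k`, `f0`, `edges`, `counts`,
#'   `vertices`, the incidence table `inc`, and per-(vertex, side) symbol
#'   sets `sym`.
#' @export
build_explicit_graph <- function(seqs, k, f0 = 1L) {
  cnt <- oracle_edge_counts(seqs, k)
  keep <- cnt$count >= f0
  edges <- cnt$mer[keep]
  counts <- cnt$count[keep]
  inc <- if (length(edges))
    unique(.incidences_vec(edges, k))
  else
    data.frame(edge = character(0), vertex = character(0),
               side = character(0), symbol = character(0))
  vertices <- sort(unique(inc$vertex))
  key <- paste(inc$vertex, inc$side)
  sym <- lapply(split(inc$symbol, key), unique)
  structure(list(k = k, f0 = f0, edges = edges, counts = counts,
                 vertices = vertices, inc = inc, sym = sym),
            class = "explicit_dbg")
}

#' @export
print.explicit_dbg <- function(x, ...) {
  cat("<explicit_dbg> k =", x$k, " f0 =", x$f0, ":",
      length(x$vertices), "vertices,", length(x$edges), "edges\n")
  invisible(x)
}

.side_syms <- function(g, vertex, side) {
  s <- g$sym[[paste(vertex, side)]]
  if (is.null(s)) character(0) else s
}

# canonical presentation of a cyclic spelling: over both orientations and
# rotations starting at the smallest canonical k-mer, the least spelling
.cycle_canonical <- function(s, k) {
  n <- nchar(s) - k + 1L
  circ <- substr(s, 1L, n)
  best <- NULL
  for (c0 in c(circ, .rc(circ))) {
    d <- paste0(c0, c0, substr(c0, 1L, min(nchar(c0), k)))
    win <- substring(d, 1:n, 1:n + k - 1L)
    cm <- .canon(win)
    for (i in which(cm == min(cm))) {
      cand <- substr(d, i, i + n + k - 2L)
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

# walk from `start` out of side s over the explicit (possibly restricted)
# symbol maps; returns spelling in walked orientation, vertices collected,
# and whether the walk closed a cycle
.oracle_walk <- function(g, start, s, sym = g$sym) {
  side_syms <- function(v, sd) {
    x <- sym[[paste(v, sd)]]
    if (is.null(x)) character(0) else x
  }
  vhat <- start
  cur <- if (s == "back") start else .rc(start)
  spelling <- cur
  verts <- character(0)
  cycle <- FALSE
  k <- g$k
  repeat {
    exit_s <- if (cur == vhat) "back" else "front"
    syms <- side_syms(vhat, exit_s)
    if (length(syms) != 1L) break
    ext <- if (exit_s == "back") syms else .comp1(syms)
    w <- paste0(substr(cur, 2L, k), ext)
    what <- .canon(w)
    if (what == vhat) break          # loop edge flanks
    if (what == start) { cycle <- TRUE; break }
    entr <- if (w == what) "front" else "back"
    if (length(side_syms(what, entr)) != 1L) break
    spelling <- paste0(spelling, ext)
    verts <- c(verts, what)
    cur <- w
    vhat <- what
  }
  list(spelling = spelling, vertices = verts, cycle = cycle)
}

# maximal unitigs over arbitrary symbol maps (used for both the full graph
# and path-cover-restricted subgraphs)
.oracle_extract <- function(g, sym) {
  visited <- new.env(parent = emptyenv())
  out <- character(0)
  vc <- integer(0)
  cy <- logical(0)
  k <- g$k
  for (v in g$vertices) {
    if (!is.null(visited[[v]])) next
    wb <- .oracle_walk(g, v, "back", sym)
    if (wb$cycle) {
      s <- .cycle_canonical(wb$spelling, k)
      cycle <- TRUE
      got <- c(v, wb$vertices)
    } else {
      wf <- .oracle_walk(g, v, "front", sym)
      s <- paste0(.rc(wf$spelling),
                  substr(wb$spelling, k + 1L, nchar(wb$spelling)))
      s <- min(s, .rc(s))
      cycle <- FALSE
      got <- c(v, wb$vertices, wf$vertices)
    }
    for (x in got) visited[[x]] <- TRUE
    out <- c(out, s)
    vc <- c(vc, nchar(s) - k + 1L)
    cy <- c(cy, cycle)
  }
  o <- order(out)
  data.frame(spelling = out[o], vertex_count = vc[o], is_cycle = cy[o],
             stringsAsFactors = FALSE)
}

#' Brute-force maximal unitigs
#'
#' Literal implementation over the explicit incidence lists: an edge is
#' internal to a maximal unitig iff both of its endpoint sides carry exactly
#' one distinct edge (loops are never internal); chains of internal edges
#' are walked and spelled. Branch-free cycles are emitted once, rotated to
#' a canonical presentation.
#'
#' @param g an `explicit_dbg`.
#' @return a data frame with columns `spelling` (canonical orientation,
#'   sorted), `vertex_count`, `is_cycle`.
#' @export
oracle_unitigs <- function(g) {
  stopifnot(inherits(g, "explicit_dbg"))
  .oracle_extract(g, g$sym)
}

#' Exhaustively enumerate maximal vertex-disjoint path covers
#'
#' Searches all subsets of the non-loop edges; a subset is a maximal path
#' cover iff no vertex side carries two subset edges, no subset component is
#' a cycle, and no excluded edge could still join two different paths (both
#' its endpoint sides unused and its endpoints in different components).
#' Each cover is reported as its sorted set of canonical path spellings;
#' distinct covers are deduplicated. Only feasible for tiny graphs.
#'
#' @param g an `explicit_dbg`.
#' @param limit refuse to enumerate more than this many subsets.
#' @return a list of character vectors (each a sorted spelling set).
#' @export
oracle_path_covers <- function(g, limit = 2^16) {
  stopifnot(inherits(g, "explicit_dbg"))
  k <- g$k
  inc_list <- lapply(g$edges, .incidences, k = k)
  nonloop <- vapply(inc_list, function(d) d$vertex[1] != d$vertex[2],
                    logical(1))
  el <- inc_list[nonloop]
  m <- length(el)
  if (2^m > limit) stop("graph too large for exhaustive path-cover search")
  vid <- seq_along(g$vertices)
  names(vid) <- g$vertices
  covers <- list()
  seen <- character(0)
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    used <- character(0)
    parent <- vid
    findp <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    ok <- TRUE
    for (j in sel) {
      d <- el[[j]]
      ks <- paste(d$vertex, d$side)
      if (any(ks %in% used)) { ok <- FALSE; break }
      used <- c(used, ks)
      a <- findp(vid[[d$vertex[1]]]); b <- findp(vid[[d$vertex[2]]])
      if (a == b) { ok <- FALSE; break }  # would close a cycle
      parent[a] <- b
    }
    if (!ok) next
    maximal <- TRUE
    for (j in setdiff(seq_len(m), sel)) {
      d <- el[[j]]
      ks <- paste(d$vertex, d$side)
      if (!any(ks %in% used) &&
          findp(vid[[d$vertex[1]]]) != findp(vid[[d$vertex[2]]])) {
        maximal <- FALSE
        break
      }
    }
    if (!maximal) next
    sym <- list()
    for (j in sel) {
      d <- el[[j]]
      for (r in 1:2) {
        key <- paste(d$vertex[r], d$side[r])
        sym[[key]] <- unique(c(sym[[key]], d$symbol[r]))
      }
    }
    spellings <- sort(.oracle_extract(g, sym)$spelling)
    id <- paste(spellings, collapse = " ")
    if (!(id %in% seen)) {
      seen <- c(seen, id)
      covers[[length(covers) + 1L]] <- spellings
    }
  }
  covers
}

#' Validate a path cover against the explicit graph
#'
#' Checks that the records partition the vertex set (vertex-disjoint and
#' covering), that every consecutive (k+1)-mer of every spelling is an edge
#' of the graph, that no vertex side is used by more than one cover edge,
#' and maximality: no non-loop edge of the graph has both of its endpoint
#' sides unused by the cover.
#'
#' @param g an `explicit_dbg`.
#' @param records a data frame with columns `spelling` and `is_cycle` (as
#'   returned by [extract_unitigs()]), or a character vector of spellings.
#' @return `TRUE` if valid, otherwise `FALSE` with attribute `"reason"`.
#' @export
validate_path_cover <- function(g, records) {
  stopifnot(inherits(g, "explicit_dbg"))
  if (is.character(records))
    records <- data.frame(spelling = records,
                          is_cycle = FALSE, stringsAsFactors = FALSE)
  k <- g$k
  fail <- function(msg) structure(FALSE, reason = msg)
  spell <- records$spelling
  cyc <- if (is.null(records$is_cycle)) rep(FALSE, length(spell))
         else records$is_cycle
  # a cyclic record of n vertices spells n edges: the wrap edge is the
  # window closing the circular sequence (append the k-th symbol)
  full <- ifelse(cyc, paste0(spell, substr(spell, k, k)), spell)
  kmers <- .canon(as.character(unlist(lapply(spell, .windows, j = k),
                                      use.names = FALSE)))
  if (length(kmers) != length(g$vertices) ||
      !identical(sort(kmers), g$vertices))
    return(fail("records do not partition the vertex set"))
  zc <- .canon(as.character(unlist(lapply(full, .windows, j = k + 1L),
                                   use.names = FALSE)))
  bad <- setdiff(zc, g$edges)
  if (length(bad))
    return(fail(paste("spelled edge not solid:", bad[1])))
  used <- character(0)
  if (length(zc)) {
    inc <- .incidences_vec(zc, k)
    key <- paste(inc$vertex, inc$side)
    # a palindromic window incides twice identically; count it once
    in_edge <- paste(rep(seq_along(zc), each = 2L), key, inc$symbol)
    key <- key[!duplicated(in_edge)]
    if (anyDuplicated(key))
      return(fail(paste("vertex side used twice:", key[duplicated(key)][1])))
    used <- key
  }
  if (length(g$edges)) {
    ginc <- .incidences_vec(g$edges, k)
    odd <- seq(1L, nrow(ginc), by = 2L)
    loop <- ginc$vertex[odd] == ginc$vertex[odd + 1L]
    gk1 <- paste(ginc$vertex, ginc$side)[odd]
    gk2 <- paste(ginc$vertex, ginc$side)[odd + 1L]
    free <- !loop & !(gk1 %in% used) & !(gk2 %in% used)
    if (any(free))
      return(fail(paste("cover not maximal: edge", g$edges[free][1],
                        "still admissible")))
  }
  TRUE
}
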