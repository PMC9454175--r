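# Piecewise traversals: automaton states over the edge set, and maximal
# unitig / path extraction over the vertex set.

#' Compute the automaton state of every vertex
#'
#' Initializes every vertex automaton with the edge-less initial state and
#' folds in the two endpoint inputs of each edge. In `"unitigs"` mode every
#' edge is fed, and the result is independent of edge order (the side-state
#' of a side depends only on the set of distinct symbols fed to it). In
#' `"path-cover"` mode the edges are examined in a deterministic order
#' derived from `order_seed`, and an edge is admitted -- both inputs fed --
#' only if both of its endpoint sides are still edge-less; loops are never
#' admitted. The admitted subgraph is branch-free: no side ever reaches the
#' `multi` state.
#'
#' @param es an `edge_spectrum`.
#' @param h an `mphf` built over `extract_vertices(es)`.
#' @param mode `"unitigs"` or `"path-cover"`.
#' @param order_seed integer seed fixing the path-cover edge admission
#'   order (ignored in unitig mode).
#' @return an object of class `state_table`: integer state codes indexed by
#'   hash value, plus `k`, `n` and `mode`.
#' @export
compute_states <- function(es, h, mode = c("unitigs", "path-cover"),
                           order_seed = 1L) {
  stopifnot(inherits(es, "edge_spectrum"), inherits(h, "mphf"))
  mode <- match.arg(mode)
  if (es$k != h$k) stop("edge spectrum and hash have different k")
  pc <- mode == "path-cover"
  ord <- if (pc && es$m > 0L) {
    set.seed(as.integer(order_seed) %% .Machine$integer.max)
    sample.int(es$m)
  } else integer(0)
  states <- cpp_compute_states(es$mer, h$ptr, es$k, pc, ord)
  structure(list(states = states, k = es$k, n = h$n, mode = mode,
                 order_seed = as.integer(order_seed)),
            class = "state_table")
}

#' @export
print.state_table <- function(x, ...) {
  cat("<state_table>", x$n, "vertices, k =", x$k, ", mode =", x$mode, "\n")
  invisible(x)
}

#' Is a vertex flanking?
#'
#' A vertex is an endpoint of its maximal unitig with respect to a walk
#' leaving through side `side` iff (1) its own state class is not
#' unique-front unique-back, or (2) the unique edge at that side leads to a
#' neighbor whose meeting side has more than one incident edge (equivalently
#' the neighbor's class is fuzzy on the meeting side). A loop edge at the
#' side also flanks the vertex.
#'
#' @param v_hat canonical k-mer of the vertex.
#' @param side `"front"` or `"back"`: the side the walk would exit through.
#' @param table a `state_table`.
#' @param h the `mphf` used to build `table`.
#' @return logical.
#' @export
is_flanking <- function(v_hat, side, table, h) {
  stopifnot(inherits(table, "state_table"), inherits(h, "mphf"))
  side <- match.arg(side, c("front", "back"))
  q <- table$states[mphf_query(h, v_hat) + 1L]
  if (dfa_state_class(q) != "unique-front unique-back") return(TRUE)
  w <- cpp_walk_unitig(v_hat, if (side == "front") 0L else 1L,
                       table$states, h$ptr, table$k)
  # the walk advances past v_hat only when the neighbor's meeting side is
  # unique and the edge is not a loop; otherwise v_hat flanks
  nchar(w$spelling) == table$k && !w$is_cycle
}

#' Walk a maximal-unitig subpath
#'
#' Starting at an (unvisited) vertex and exiting through the given side,
#' repeatedly decodes the unique incident edge from the vertex state,
#' crosses to the neighbor's entrance side and switches to its other side,
#' until a flanking vertex halts the walk. If the walk returns to its start
#' the containing component is a branch-free cycle.
#'
#' @inheritParams is_flanking
#' @return a list: `spelling` (in the orientation walked, beginning with the
#'   start vertex's exiting form), `terminal` (canonical k-mer of the last
#'   vertex), `terminal_side`, `is_cycle`.
#' @export
walk_unitig <- function(v_hat, side, table, h) {
  stopifnot(inherits(table, "state_table"), inherits(h, "mphf"))
  side <- match.arg(side, c("front", "back"))
  w <- cpp_walk_unitig(v_hat, if (side == "front") 0L else 1L,
                       table$states, h$ptr, table$k)
  w$terminal_side <- if (w$terminal_side == 0L) "front" else "back"
  w
}

#' Extract all maximal unitigs (or cover paths)
#'
#' Iterates over the vertices; for each not yet visited vertex, walks out of
#' both sides, glues the two subpath spellings at the vertex, and emits the
#' maximal unitig once, in canonical orientation (the lexicographic minimum
#' of the spelling and its reverse complement). A branch-free cycle is
#' emitted once as a cyclic record, rotated so that the smallest canonical
#' k-mer leads, which makes output independent of iteration order. Applied
#' to a path-cover state table, the same procedure emits exactly the
#' admitted maximal paths.
#'
#' @param vs a `vertex_spectrum`.
#' @param table a `state_table` over the same graph.
#' @param h the `mphf` used to build `table`.
#' @return an object of class `unitig_set`: a data frame with columns
#'   `spelling`, `vertex_count`, `is_cycle`, sorted by spelling, with
#'   attributes `k` and `mode`.
#' @export
extract_unitigs <- function(vs, table, h) {
  stopifnot(inherits(vs, "vertex_spectrum"), inherits(table, "state_table"),
            inherits(h, "mphf"))
  if (vs$n != table$n) stop("vertex spectrum and state table sizes differ")
  r <- cpp_extract_unitigs(vs$mer, table$states, h$ptr, table$k)
  d <- data.frame(spelling = r$spelling, vertex_count = r$vertex_count,
                  is_cycle = r$is_cycle, stringsAsFactors = FALSE)
  d <- d[order(d$spelling), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("unitig_set", "data.frame")
  attr(d, "k") <- table$k
  attr(d, "mode") <- table$mode
  d
}

#' @export
print.unitig_set <- function(x, ...) {
  cat("<unitig_set>", nrow(x), "records, k =", attr(x, "k"),
      ", mode =", attr(x, "mode"), "\n")
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}
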