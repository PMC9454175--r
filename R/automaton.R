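# The per-vertex DFA: 36 states (6 side-states per side), inputs (side,
# symbol), transition function, and the per-endpoint edge encoding.

SIDE_STATES <- c("none", "multi", "unique_A", "unique_C", "unique_G",
                 "unique_T")

.side_code <- function(side) {
  side <- match.arg(side, c("front", "back"))
  if (side == "front") 0L else 1L
}
.sym_code <- function(symbol) {
  i <- match(symbol, c("A", "C", "G", "T"))
  if (is.na(i)) stop("symbol must be one of A, C, G, T")
  i - 1L
}

#' Construct a DFA state code from its two side states
#'
#' A vertex automaton state is a pair of side states, one per vertex side,
#' each of: `none` (0 incident edges), `multi` (more than one distinct
#' incident edge), or `unique_A`/`unique_C`/`unique_G`/`unique_T` (exactly
#' one, encoded by its symbol). There are 6 x 6 = 36 states, encoded as
#' `front * 6 + back` in `[0, 36)` -- 6 bits suffice. The initial state `q0`
#' is `(none, none)` (code 0).
#'
#' @param front,back side states (elements of
#'   `c("none","multi","unique_A","unique_C","unique_G","unique_T")`).
#' @return integer state code in `[0, 36)`.
#' @export
dfa_state_code <- function(front = "none", back = "none") {
  f <- match(front, SIDE_STATES)
  b <- match(back, SIDE_STATES)
  if (is.na(f) || is.na(b)) stop("unknown side state")
  (f - 1L) * 6L + (b - 1L)
}

#' Decompose a DFA state code into its side states
#' @param q integer state code in `[0, 36)`.
#' @return a list with elements `front` and `back`.
#' @export
dfa_state_sides <- function(q) {
  q <- as.integer(q)
  if (any(q < 0L | q > 35L)) stop("state code must be in [0, 36)")
  list(front = SIDE_STATES[q %/% 6L + 1L], back = SIDE_STATES[q %% 6L + 1L])
}

#' DFA transition function
#'
#' Feeds the input (side, symbol) -- an edge incident to that side, encoded
#' by the symbol -- to a vertex automaton in state `q`. Only the addressed
#' side updates: `none` becomes `unique_c`; `unique_c` stays on the same
#' symbol (self-transition) and becomes `multi` on a different one; `multi`
#' absorbs. The codomain excludes the initial state: feeding any input
#' leaves at least one edge observed.
#'
#' @param q integer state code in `[0, 36)`.
#' @param side `"front"` or `"back"`.
#' @param symbol one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return the new state code.
#' @examples
#' dfa_transit(dfa_state_code(), "back", "C")
#' @export
dfa_transit <- function(q, side, symbol) {
  cpp_transit(as.integer(q), .side_code(side), .sym_code(symbol))
}

#' State class of a DFA state
#'
#' One of the four classes used by the traversal: a side is "fuzzy" when it
#' has 0 or more than 1 distinct incident edges (`none` or `multi`), and
#' "unique" when it has exactly one.
#'
#' @param q integer state code in `[0, 36)`.
#' @return one of `"fuzzy-front fuzzy-back"`, `"fuzzy-front unique-back"`,
#'   `"unique-front fuzzy-back"`, `"unique-front unique-back"`.
#' @export
dfa_state_class <- function(q) {
  s <- dfa_state_sides(q)
  ff <- s$front %in% c("none", "multi")
  fb <- s$back %in% c("none", "multi")
  paste0(if (ff) "fuzzy-front" else "unique-front", " ",
         if (fb) "fuzzy-back" else "unique-back")
}

#' Per-endpoint DFA inputs of an edge
#'
#' Decomposes a canonical (k+1)-mer edge into its two endpoint incidences.
#' The edge exits through its prefix k-mer's back iff that prefix is
#' canonical (else through the front), and enters through its suffix
#' k-mer's front iff that suffix is canonical (else through the back). For
#' each endpoint the fixed form of the edge containing the endpoint's
#' canonical k-mer is used, so the encoding symbol is the edge's terminal
#' symbol, complemented when the incidence is on the front.
#'
#' @param edge a (k+1)-mer; either orientation may be given, since the two
#'   incidences are invariant under reverse complement (they are computed
#'   on the canonical form).
#' @param k the k-mer length.
#' @return a list with elements `u` and `v`, each a list `vertex` (canonical
#'   k-mer), `side` (`"front"`/`"back"`), `symbol`.
#' @examples
#' edge_dfa_inputs("CGAT", 3)
#' @export
edge_dfa_inputs <- function(edge, k) {
  r <- cpp_edge_inputs(edge, as.integer(k))
  conv <- function(x)
    list(vertex = x$vertex, side = if (x$side == 0L) "front" else "back",
         symbol = x$symbol)
  list(u = conv(r$u), v = conv(r$v))
}

#' Is a side of a state fuzzy?
#'
#' True iff the vertex has 0 or more than 1 distinct edges at that side.
#'
#' @inheritParams dfa_transit
#' @return logical.
#' @export
is_fuzzy_side <- function(q, side) {
  s <- dfa_state_sides(q)
  st <- if (match.arg(side, c("front", "back")) == "front") s$front else s$back
  st %in% c("none", "multi")
}

#' Unique-edge symbol at a side
#'
#' Returns the symbol encoding the single edge incident to the given side.
#' It is an error to ask for the extension of a fuzzy side.
#'
#' @inheritParams dfa_transit
#' @return one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @export
edge_extension <- function(q, side) {
  s <- dfa_state_sides(q)
  st <- if (match.arg(side, c("front", "back")) == "front") s$front else s$back
  if (st %in% c("none", "multi"))
    stop("edge_extension is defined only for a side with exactly one edge")
  sub("unique_", "", st)
}

#' Entrance and exit sides of a vertex for an observed k-mer form
#'
#' When a walk observes a vertex as the k-mer `observed` (either the
#' canonical form `v_hat` itself or its reverse complement), it exits
#' through the back iff the observed form is canonical, and enters through
#' the front iff it is canonical; the two are always opposite sides.
#'
#' @param v_hat canonical k-mer of the vertex.
#' @param observed the observed k-mer form (`v_hat` or its reverse
#'   complement).
#' @return `"front"` or `"back"`.
#' @export
exit_side <- function(v_hat, observed) {
  .check_observed(v_hat, observed)
  if (identical(observed, v_hat)) "back" else "front"
}

#' @rdname exit_side
#' @export
entrance_side <- function(v_hat, observed) {
  .check_observed(v_hat, observed)
  if (identical(observed, v_hat)) "front" else "back"
}

.check_observed <- function(v_hat, observed) {
  if (!identical(observed, v_hat) &&
      !identical(observed, as.character(cpp_revcomp(v_hat))))
    stop("observed form must be the vertex or its reverse complement")
  invisible(TRUE)
}
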