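SIDES <- c("none", "multi", "unique_A", "unique_C", "unique_G", "unique_T")

test_that("the transition function is total and never returns the start state", {
  q0 <- dfa_state_code("none", "none")
  for (f in SIDES) for (b in SIDES) {
    q <- dfa_state_code(f, b)
    for (side in c("front", "back")) for (sym in c("A", "C", "G", "T")) {
      q2 <- dfa_transit(q, side, sym)
      expect_true(q2 >= 0 && q2 <= 35)
      expect_true(q2 != q0)
      # the unaddressed side never changes
      other <- if (side == "front") "back" else "front"
      expect_identical(dfa_state_sides(q2)[[other]],
                       dfa_state_sides(q)[[other]])
    }
  }
})

test_that("single transitions follow the side-state rules", {
  q0 <- dfa_state_code()
  expect_identical(dfa_state_sides(dfa_transit(q0, "back", "C")),
                   list(front = "none", back = "unique_C"))
  q <- dfa_state_code("unique_A", "none")
  expect_identical(dfa_state_sides(dfa_transit(q, "front", "G"))$front,
                   "multi")
  q2 <- dfa_state_code("unique_T", "multi")
  expect_identical(dfa_transit(q2, "front", "T"), q2) # self-transition
})

test_that("a side's final state depends only on the set of symbols fed", {
  syms <- c("A", "C", "G", "T")
  for (len in 1:4) {
    combos <- expand.grid(rep(list(syms), len), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      seqs <- as.character(combos[r, ])
      q <- dfa_state_code()
      for (s in seqs) q <- dfa_transit(q, "back", s)
      expected <- if (length(unique(seqs)) == 1L)
        paste0("unique_", seqs[1]) else "multi"
      expect_identical(dfa_state_sides(q)$back, expected)
      expect_identical(dfa_state_sides(q)$front, "none")
    }
  }
})

test_that("state codes fit six bits and classes partition the state space", {
  codes <- vapply(SIDES, function(f) vapply(SIDES, function(b)
    dfa_state_code(f, b), integer(1)), integer(6))
  expect_equal(sort(as.vector(codes)), 0:35)
  cls <- vapply(0:35, dfa_state_class, character(1))
  expect_equal(sort(unique(cls)),
               sort(c("fuzzy-front fuzzy-back", "fuzzy-front unique-back",
                      "unique-front fuzzy-back", "unique-front unique-back")))
  expect_equal(as.vector(table(cls)[c("fuzzy-front fuzzy-back",
                                      "unique-front unique-back")]),
               c(4L, 16L))
})

test_that("edges decompose into endpoint inputs by the canonicality rules", {
  inc_set <- function(r) {
    ids <- sort(c(paste(r$u$vertex, r$u$side, r$u$symbol),
                  paste(r$v$vertex, r$v$side, r$v$symbol)))
    ids
  }
  # the 4-mer CGAT exits CGA through its back and enters ATC through its
  # back (suffix GAT is non-canonical)
  r <- edge_dfa_inputs("CGAT", 3)
  expect_equal(inc_set(r), c("ATC back G", "CGA back T"))
  # incidences are orientation-invariant
  expect_equal(inc_set(edge_dfa_inputs("ATCG", 3)), inc_set(r))
  r2 <- edge_dfa_inputs("CTAA", 3)
  expect_equal(r2$u, list(vertex = "CTA", side = "back", symbol = "A"))
  expect_equal(r2$v, list(vertex = "TAA", side = "front", symbol = "C"))
  # palindromic edge: the two endpoint incidences coincide
  r3 <- edge_dfa_inputs("TGCA", 3)
  expect_equal(r3$u, r3$v)
  expect_equal(r3$u$vertex, "GCA")
  expect_error(edge_dfa_inputs("TGCAA", 3), "mer")
  expect_error(edge_dfa_inputs("CGNT", 3), "non-ACGT")
})

test_that("fuzzy-side and edge-extension helpers decode states", {
  expect_true(is_fuzzy_side(dfa_state_code(), "front"))
  q <- dfa_state_code("unique_A", "multi")
  expect_false(is_fuzzy_side(q, "front"))
  expect_true(is_fuzzy_side(q, "back"))
  expect_equal(edge_extension(dfa_state_code("unique_G", "none"), "front"),
               "G")
  expect_equal(edge_extension(dfa_state_code("none", "unique_T"), "back"),
               "T")
  expect_error(edge_extension(dfa_state_code("multi", "none"), "front"),
               "exactly one")
})

test_that("entrance and exit sides are opposite and fixed by canonicality", {
  expect_equal(exit_side("CGA", "CGA"), "back")
  expect_equal(entrance_side("CGA", "CGA"), "front")
  expect_equal(exit_side("ATC", "GAT"), "front")
  expect_equal(entrance_side("ATC", "GAT"), "back")
  set.seed(3)
  for (i in 1:20) {
    v <- canonical_mer(rand_mers(1, 9, seed = i))$mer
    obs <- if (i %% 2) v else reverse_complement(v)
    expect_true(exit_side(v, obs) != entrance_side(v, obs))
  }
  expect_error(exit_side("CGA", "AAA"), "reverse complement")
})
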