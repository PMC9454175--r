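we_graph <- function(mode = "unitigs", order_seed = 1) {
  es <- enumerate_edges(worked_example(), k = 3, f0 = 1)
  vs <- extract_vertices(es)
  h <- build_mphf(vs, seed = 1)
  st <- compute_states(es, h, mode = mode, order_seed = order_seed)
  list(es = es, vs = vs, h = h, st = st)
}

state_of <- function(g, v) {
  dfa_state_sides(g$st$states[mphf_query(g$h, v) + 1])
}

test_that("automaton states on the worked example match the known incidences", {
  g <- we_graph()
  expect_equal(state_of(g, "ATC"),
               list(front = "unique_C", back = "multi"))
  expect_equal(state_of(g, "AGA"),
               list(front = "unique_A", back = "multi"))
  expect_equal(state_of(g, "TAA"),
               list(front = "unique_C", back = "unique_G"))
  expect_equal(state_of(g, "CGA"),
               list(front = "none", back = "unique_T"))
  # loop vertex: the palindromic edge TGCA sits on GCA's front
  expect_equal(state_of(g, "GCA"),
               list(front = "unique_T", back = "unique_T"))
})

test_that("states are independent of the edge iteration order", {
  g <- we_graph()
  es_rev <- g$es
  es_rev$mer <- rev(es_rev$mer)
  es_rev$count <- rev(es_rev$count)
  st2 <- compute_states(es_rev, g$h, mode = "unitigs")
  expect_identical(g$st$states, st2$states)
})

test_that("loop edges produce side counts matching the explicit incidences", {
  es <- enumerate_edges("AAAA", k = 3, f0 = 1)
  vs <- extract_vertices(es)
  h <- build_mphf(vs, seed = 1)
  st <- compute_states(es, h)
  expect_equal(dfa_state_sides(st$states[1]),
               list(front = "unique_A", back = "unique_A"))
  u <- extract_unitigs(vs, st, h)
  expect_equal(u$spelling, "AAA")
  expect_equal(u$vertex_count, 1L)
})

test_that("flanking detection follows both the class and the neighbor rule", {
  g <- we_graph()
  expect_true(is_flanking("AGA", "back", g$st, g$h))   # back has 2 edges
  expect_true(is_flanking("AGA", "front", g$st, g$h))  # class not u-f u-b
  expect_false(is_flanking("TAA", "front", g$st, g$h))
  expect_false(is_flanking("TAA", "back", g$st, g$h))
  # CTA's back neighbor TAA is unique at the meeting side, but CTA's own
  # front has no edge: class flanks it
  expect_true(is_flanking("CTA", "front", g$st, g$h))
  # AAG is internal: unique both sides, neighbors unique at meeting sides
  expect_false(is_flanking("AAG", "back", g$st, g$h))
  # GCA: the loop at its front flanks it despite a unique side state
  expect_true(is_flanking("GCA", "front", g$st, g$h))
})

test_that("directional walks stitch the known unitig and stop at flanks", {
  g <- we_graph()
  w <- walk_unitig("CTA", "back", g$st, g$h)
  expect_equal(w$spelling, "CTAAGA")
  expect_equal(w$terminal, "AGA")
  expect_false(w$is_cycle)
  # walking out of a side with no edge stays put
  w2 <- walk_unitig("CTA", "front", g$st, g$h)
  expect_equal(w2$spelling, reverse_complement("CTA"))
  expect_equal(w2$terminal, "CTA")
})

test_that("the worked example compacts into its four maximal unitigs", {
  g <- we_graph()
  u <- extract_unitigs(g$vs, g$st, g$h)
  expect_equal(nrow(u), 4L)
  expect_true("CTAAGA" %in% u$spelling)
  expect_equal(sum(u$vertex_count), 10L)       # vertex decomposition
  expect_true(all(!u$is_cycle))
  expect_equal(sort(spelled_kmers(u$spelling, 3)), g$vs$mer)
  expect_true(all_edges_solid(u, g$es))
})

test_that("a circular input yields a single cyclic record, emitted once", {
  circ <- random_genome(60, seed = 1)
  inp <- paste0(circ, substr(circ, 1, 7))
  # premise: no repeated canonical (k-1)-mer around the circle
  inner <- valid_jmers(paste0(circ, substr(circ, 1, 6)), 6)$mer[1:60]
  expect_false(any(duplicated(canonical_mer(inner)$mer)))
  es <- enumerate_edges(inp, k = 7, f0 = 1)
  vs <- extract_vertices(es)
  h <- build_mphf(vs, seed = 2)
  st <- compute_states(es, h)
  u <- extract_unitigs(vs, st, h)
  expect_equal(nrow(u), 1L)
  expect_true(u$is_cycle)
  expect_equal(u$vertex_count, 60L)
  expect_equal(sort(spelled_kmers(u$spelling, 7)), vs$mer)
  # rotation rule: the smallest canonical k-mer leads
  expect_equal(canonical_mer(substr(u$spelling, 1, 7))$mer, vs$mer[1])
  expect_true(all_edges_solid(u, es))
})

test_that("path-cover states admit edges only into free sides", {
  for (s in c(1, 2, 7, 19)) {
    g <- we_graph(mode = "path-cover", order_seed = s)
    sides <- lapply(g$st$states, dfa_state_sides)
    expect_false(any(vapply(sides, function(x)
      any(unlist(x) == "multi"), logical(1))))
    u <- extract_unitigs(g$vs, g$st, g$h)
    sp <- sort(u$spelling)
    covers <- list(sort(c("CCTC", "CGA", "CTAAGATGC")),
                   sort(c("CCTCTTAG", "CGATGC")))
    expect_true(identical(sp, covers[[1]]) || identical(sp, covers[[2]]))
  }
})

test_that("a single simple path is admitted whole regardless of order", {
  g <- random_genome(80, seed = 23)
  es <- enumerate_edges(g, k = 15, f0 = 1)
  vs <- extract_vertices(es)
  h <- build_mphf(vs, seed = 1)
  for (s in 1:5) {
    st <- compute_states(es, h, mode = "path-cover", order_seed = s)
    u <- extract_unitigs(vs, st, h)
    expect_equal(nrow(u), 1L)
    expect_equal(u$spelling, min(g, as.character(reverse_complement(g))))
  }
})

test_that("identical input and seed give byte-identical output", {
  g <- random_genome(400, seed = 31)
  reads <- simulate_reads(g, 50, 15, 0.01, seed = 5)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_unitigs(compact_dbg(reads, k = 15, f0 = 2, mode = "path-cover",
                            seed = 99), f1)
  write_unitigs(compact_dbg(reads, k = 15, f0 = 2, mode = "path-cover",
                            seed = 99), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
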