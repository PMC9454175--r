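test_that("the explicit graph materializes the worked example", {
  g <- build_explicit_graph(worked_example(), 3, 1)
  expect_length(g$vertices, 10L)
  expect_length(g$edges, 10L)
  g2 <- build_explicit_graph(worked_example(), 3, 2)
  expect_length(g2$edges, 2L)
  expect_length(g2$vertices, 3L)
  g3 <- build_explicit_graph("CGAT", 3, 1)
  expect_length(g3$edges, 1L)
  expect_length(g3$vertices, 2L)
  g4 <- build_explicit_graph("AAAA", 3, 1) # loop: one vertex, one edge
  expect_length(g4$edges, 1L)
  expect_length(g4$vertices, 1L)
})

test_that("brute-force unitigs match the worked example", {
  u <- oracle_unitigs(build_explicit_graph(worked_example(), 3, 1))
  expect_equal(nrow(u), 4L)
  expect_true("CTAAGA" %in% u$spelling)
  expect_equal(sum(u$vertex_count), 10L)
})

test_that("exhaustive search finds exactly the two known path covers", {
  g <- build_explicit_graph(worked_example(), 3, 1)
  cv <- oracle_path_covers(g)
  expect_length(cv, 2L)
  ids <- sort(vapply(cv, paste, character(1), collapse = " "))
  expect_equal(ids, sort(c(paste(sort(c("CTAAGATGC", "CGA", "CCTC")),
                                 collapse = " "),
                           paste(sort(c("CCTCTTAG", "CGATGC")),
                                 collapse = " "))))
  for (c0 in cv) expect_true(validate_path_cover(g, c0))
  # a single-path graph has exactly one cover
  p <- build_explicit_graph("ACGTTCA", 3, 1)
  expect_length(oracle_path_covers(p), 1L)
})

test_that("the cover validator rejects broken covers", {
  g <- build_explicit_graph(worked_example(), 3, 1)
  cv <- oracle_path_covers(g)[[1]]
  expect_false(isTRUE(validate_path_cover(g, cv[-1]))) # not covering
  # two singleton fragments of one path are not maximal
  frag <- c(setdiff(cv, "CCTC"), "CTC", "AGG")
  v <- validate_path_cover(g, frag)
  expect_false(isTRUE(v))
  expect_match(attr(v, "reason"), "maximal")
})

test_that("genome and read simulation are deterministic and faithful", {
  g1 <- random_genome(500, seed = 7)
  expect_identical(g1, random_genome(500, seed = 7))
  expect_false(identical(g1, random_genome(500, seed = 8)))
  expect_equal(nchar(g1), 500L)
  r1 <- simulate_reads(g1, 50, 10, 0.01, seed = 3)
  expect_identical(r1, simulate_reads(g1, 50, 10, 0.01, seed = 3))
  expect_length(r1, ceiling(10 * 500 / 50))
  expect_true(all(nchar(r1) <= 50))
  # error-free reads align exactly to the genome on one strand
  r0 <- simulate_reads(g1, 40, 5, 0, seed = 4)
  fwd <- vapply(r0, function(x) grepl(x, g1, fixed = TRUE), logical(1))
  rev <- vapply(as.character(reverse_complement(unname(r0))),
                function(x) grepl(x, g1, fixed = TRUE), logical(1))
  expect_true(all(fwd | rev))
})

test_that("a genome without repeated (k-1)-mers is one maximal unitig", {
  g <- random_genome(300, seed = 40)
  k <- 21
  inner <- valid_jmers(g, k - 1)$mer
  expect_false(any(duplicated(canonical_mer(inner)$mer))) # premise
  u <- oracle_unitigs(build_explicit_graph(g, k, 1))
  expect_equal(nrow(u), 1L)
  expect_equal(u$spelling, min(g, as.character(reverse_complement(g))))
})
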