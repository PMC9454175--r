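test_that("window signature is the smallest canonical sub-mer", {
  # brute force over all 2-mer windows and their canonical forms
  brute <- function(win, m) {
    sub <- substring(win, 1:(nchar(win) - m + 1), m:nchar(win))
    min(canonical_mer(sub)$mer)
  }
  expect_equal(edge_signature("CTAA", 2), "AA")
  expect_equal(edge_signature("CTAA", 2), brute("CTAA", 2))
  expect_equal(edge_signature("AAAA", 2), "AA")
  set.seed(31)
  for (i in 1:50) {
    w <- rand_mers(1, sample(4:16, 1), seed = i)
    m <- sample(2:3, 1)
    expect_equal(edge_signature(w, m), brute(w, m))
    expect_equal(edge_signature(reverse_complement(w), m),
                 edge_signature(w, m))
  }
})

test_that("super-mer splitting conserves the l-mer stream", {
  s <- "CTAAGAT"
  sp <- split_super_mers(s, l = 4, msig = 2, bins = 8)
  got <- sort(unlist(lapply(sp$super_mer, function(x) valid_jmers(x, 4)$mer)))
  expect_equal(got, sort(valid_jmers(s, 4)$mer))
  # every window of a super-mer shares that super-mer's signature
  for (i in seq_len(nrow(sp))) {
    sigs <- vapply(valid_jmers(sp$super_mer[i], 4)$mer,
                   edge_signature, character(1), msig = 2)
    expect_length(unique(sigs), 1L)
  }
  # random sequences with Ns
  set.seed(77)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T", "N"), 120, replace = TRUE,
                      prob = c(rep(0.24, 4), 0.04)), collapse = "")
    l <- sample(c(4, 8, 16), 1)
    sp <- split_super_mers(x, l = l, msig = 3, bins = 16)
    got <- sort(unlist(lapply(sp$super_mer,
                              function(z) valid_jmers(z, l)$mer)))
    expect_equal(got, sort(valid_jmers(x, l)$mer))
  }
  # all windows sharing one signature -> a single super-mer
  one <- split_super_mers("AAAAAAA", l = 4, msig = 2, bins = 8)
  expect_equal(nrow(one), 1L)
  expect_equal(one$super_mer, "AAAAAAA")
})

test_that("edge enumeration matches the worked example", {
  S <- worked_example()
  es <- enumerate_edges(S, k = 3, f0 = 1)
  expect_equal(es$m, 10L)
  expect_true(all(es$mer == sort(es$mer)))
  # TAAG and AAGA occur twice (canonical forms CTTA and AAGA)
  expect_equal(es$count[match(c("AAGA", "CTTA"), es$mer)], c(2L, 2L))
  es2 <- enumerate_edges(S, k = 3, f0 = 2)
  expect_equal(es2$mer, c("AAGA", "CTTA"))
  es3 <- enumerate_edges("AAAA", k = 3, f0 = 1)
  expect_equal(es3$mer, "AAAA")
  expect_error(enumerate_edges(S, k = 4), "odd")
  expect_error(enumerate_edges(S, k = 3, f0 = 0), "f0")
  expect_equal(enumerate_edges(character(0), k = 3)$m, 0L)
})

test_that("edge enumeration equals a naive dictionary counter", {
  set.seed(11)
  for (i in 1:12) {
    k <- sample(c(3, 15, 31), 1)
    seqs <- vapply(seq_len(sample(1:5, 1)), function(j)
      paste(sample(c("A", "C", "G", "T", "n"), sample(50:400, 1),
                   replace = TRUE, prob = c(rep(0.245, 4), 0.02)),
            collapse = ""), character(1))
    f0 <- sample(1:2, 1)
    es <- enumerate_edges(seqs, k = k, f0 = f0)
    ref <- oracle_edge_counts(seqs, k)
    ref <- ref[ref$count >= f0, ]
    expect_equal(es$mer, ref$mer)
    expect_equal(es$count, ref$count)
    if (f0 == 1) { # count conservation over valid windows
      nwin <- sum(vapply(seqs, function(s) nrow(valid_jmers(s, k + 1)),
                         integer(1)))
      expect_equal(sum(es$count), nwin)
    }
  }
})

test_that("raising the threshold never adds edges", {
  g <- random_genome(500, seed = 9)
  reads <- simulate_reads(g, 50, 10, 0.02, seed = 10)
  prev <- NULL
  for (f0 in 1:4) {
    es <- enumerate_edges(reads, k = 15, f0 = f0)
    if (!is.null(prev)) expect_true(all(es$mer %in% prev))
    prev <- es$mer
  }
})

test_that("spilling bin buffers to disk does not change the spectrum", {
  g <- random_genome(2000, seed = 21)
  a <- enumerate_edges(g, 15, 1)
  wd <- file.path(tempdir(), "spill_test")
  dir.create(wd, showWarnings = FALSE)
  b <- enumerate_edges(g, 15, 1, memory_budget = 500, work_dir = wd)
  expect_identical(a$mer, b$mer)
  expect_identical(a$count, b$count)
  expect_length(list.files(wd, pattern = "^cdbg_bin_"), 0L) # cleaned up
})

test_that("vertex extraction yields the canonical end k-mers of the edges", {
  es <- enumerate_edges(worked_example(), k = 3, f0 = 1)
  vs <- extract_vertices(es)
  expect_equal(vs$n, 10L)
  expect_equal(vs$mer, c("AAG", "AGA", "AGG", "ATC", "ATG", "CGA", "CTA",
                         "CTC", "GCA", "TAA"))
  vs2 <- extract_vertices(enumerate_edges("AAAA", k = 3, f0 = 1))
  expect_equal(vs2$mer, "AAA")
  # membership property on random input
  g <- random_genome(300, seed = 3)
  es3 <- enumerate_edges(g, 7, 1)
  vs3 <- extract_vertices(es3)
  ends <- canonical_mer(c(substr(es3$mer, 1, 7), substr(es3$mer, 2, 8)))$mer
  expect_true(all(ends %in% vs3$mer))
  expect_true(all(vs3$mer %in% ends))
})
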