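test_that("the toy model finds, segments and scores perfect repeats", {
  m <- toy_cphmm()
  dna <- alphabet("dna")
  nl <- null_model(dna)
  h <- viterbi_search(m, seq_record("s1", "ACACAC", dna), nl)
  expect_length(h, 1)
  expect_equal(c(h[[1]]$start, h[[1]]$end), c(0, 6))
  expect_length(h[[1]]$units$rows, 3)
  expect_equal(as.integer(h[[1]]$wrap_points), c(2L, 4L))
  expect_lte(h[[1]]$viterbi_logodds, h[[1]]$forward_logodds + 1e-9)
  # symbols with low match emission: no hit
  expect_length(viterbi_search(m, seq_record("s2", "GGGGGG", dna), nl), 0)
  # flanks absorbed by the null states
  h3 <- viterbi_search(m, seq_record("s3", "GGACACGG", dna), nl)
  expect_equal(c(h3[[1]]$start, h3[[1]]$end), c(2, 6))
  # empty sequence is not an error
  expect_length(viterbi_search(m, seq_record("e", "", dna), nl), 0)
  # alphabet mismatch is
  expect_error(viterbi_search(m, seq_record("p", "ACDE", alphabet("aa")), nl),
               "alphabet mismatch")
})

test_that("partial first/last units are padded with gaps", {
  m <- toy_cphmm()
  dna <- alphabet("dna")
  h <- viterbi_search(m, seq_record("s4", "GGCACACAGG", dna),
                      null_model(dna))
  expect_identical(unname(h[[1]]$units$rows), c("-C", "AC", "AC", "A-"))
})

test_that("deletions decode as gaps in profile columns", {
  dna <- alphabet("dna")
  path <- data.frame(kind = c("M", "D", "M", "M"),
                     pos = c(1L, 2L, 1L, 2L),
                     res_idx = c(1L, NA, 2L, 3L))
  ua <- decode_units(path, "AAC", L = 2, alphabet = dna)
  expect_identical(unname(ua$rows), c("A-", "AC"))
  # a path without any wrap is not a tandem repeat
  p1 <- data.frame(kind = c("M", "M"), pos = 1:2, res_idx = 1:2)
  expect_error(decode_units(p1, "AC", L = 2, alphabet = dna),
               "not a tandem repeat")
})

test_that("window scores match exhaustive path enumeration", {
  set.seed(1234)
  for (trial in 1:30) {
    m <- random_cphmm()
    nl <- null_model(m$base$alphabet)
    win <- random_window(m)
    o <- enum_window_logodds(m, nl, win)
    expect_equal(forward_logodds(m, win, nl), o["forward"],
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(viterbi_logodds(m, win, nl), o["viterbi"],
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("appending a perfect unit increases the forward log-odds", {
  m <- toy_cphmm()
  nl <- null_model(alphabet("dna"))
  expect_gt(forward_logodds(m, "ACACAC", nl), forward_logodds(m, "ACAC", nl))
})

test_that("rotating profile columns leaves window scores unchanged", {
  set.seed(77)
  for (trial in 1:8) {
    m <- random_cphmm(L = sample(2:4, 1))
    nl <- null_model(m$base$alphabet)
    win <- random_window(m, 6)
    k <- sample(m$base$L - 1, 1)
    expect_equal(forward_logodds(m, win, nl),
                 forward_logodds(rotate_cphmm(m, k), win, nl),
                 tolerance = 1e-9)
  }
})

test_that("database search applies filters and is byte-deterministic", {
  aa <- alphabet("aa")
  set.seed(500)
  anc <- random_protein(15)
  m <- train_model_from_sim(anc, 5, 0.05, seed = 7)
  bench <- make_benchmark(1, 2, anc, n_units = 3, divergence_t = 0.05,
                          seed = 21, alphabet = aa)
  tab <- search_database(m, bench$records)
  expect_equal(nrow(tab), 1)
  expect_identical(tab$sequence_id, "pos_001")
  # filter semantics: min_units above the decoded count empties the table
  tab2 <- search_database(m, bench$records, min_units = 8)
  expect_equal(nrow(tab2), 0)
  # determinism: byte-identical reruns
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  search_database(m, bench$records, out_tsv = f1)
  search_database(m, bench$records, out_tsv = f2)
  expect_identical(readLines(f1), readLines(f2))
})
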