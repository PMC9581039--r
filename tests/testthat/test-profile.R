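test_that("build_profile counts emissions and transitions as stated", {
  aa <- alphabet("aa")
  # no-variation limit: tiny pseudocount concentrates all mass
  p <- build_profile(unit_alignment(c("AC", "AC"), alphabet = aa), 1e-9)
  expect_equal(p$L, 2L)
  expect_gt(p$match_emis[1, "A"], 1 - 1e-6)
  expect_gt(p$trans[1, "MM"], 1 - 1e-6)
  # direct count over the two row paths: M->M and M->D each once
  p2 <- build_profile(unit_alignment(c("AC", "A-"), alphabet = aa), 1e-9)
  expect_equal(p2$L, 2L)  # 50% gaps still a match column
  expect_equal(unname(p2$trans[1, c("MM", "MD")]), c(0.5, 0.5),
               tolerance = 1e-6)
  # middle column at exactly 50% gaps counts as match
  p3 <- build_profile(unit_alignment(c("A-C", "AGC"), alphabet = aa))
  expect_equal(p3$L, 3L)
  expect_error(build_profile(unit_alignment(c("--", "--", "--", "AC"),
                                            alphabet = aa)),
               "no match columns")
})

test_that("emission rows converge to the background as smoothing grows", {
  aa <- alphabet("aa")
  p <- build_profile(unit_alignment(c("ACDE", "ACDE"), alphabet = aa), 1e7)
  for (i in seq_len(p$L))
    expect_equal(unname(p$match_emis[i, ]), unname(aa$background),
                 tolerance = 1e-5)
})

test_that("circularize sets equal begin weights and per-visit exit", {
  aa <- alphabet("aa")
  p <- build_profile(unit_alignment(c("ACD", "ACD", "ACE"), alphabet = aa))
  m <- circularize(p, exit_prob = 0.1)
  expect_equal(m$begin_weights, rep(1 / 3, 3))
  # continue mass at every match state is 1 - eps
  tr <- tandemscan:::cphmm_trans(m)
  expect_equal(unname(rowSums(tr[, c("MM", "MI", "MD")]) * 0.9),
               rep(0.9, 3), tolerance = 1e-9)
  expect_error(circularize(p, exit_prob = 0), "exit_prob")
  expect_error(circularize(p, exit_prob = 1), "exit_prob")
  # removing the wrap recovers the linear profile exactly
  expect_identical(m$base, p)
  expect_silent(tandemscan:::validate_cphmm(m))
})

test_that("a deterministic match cycle accumulates (1-eps)^L continue mass", {
  dna <- alphabet("dna")
  em <- matrix(1 / 4, 3, 4, dimnames = list(NULL, dna$symbols))
  tr <- matrix(rep(c(1, 0, 0, 1, 0, 0, 1, 0, 0), each = 3), 3, 9,
               dimnames = list(NULL, colnames(toy_cphmm()$base$trans)))
  p <- structure(list(L = 3L, alphabet = dna, match_emis = em,
                      insert_emis = em, trans = tr), class = "profile_hmm")
  m <- circularize(p, exit_prob = 0.1)
  ltr <- tandemscan:::model_pack(m, null_model(dna))$lt
  cyc <- ltr[1, "MM"] + ltr[2, "MM"] + ltr[3, "MM"]
  expect_equal(unname(cyc), 3 * log(0.9), tolerance = 1e-12)
})

test_that("sampled unit lengths peak at L when indels are rare", {
  set.seed(42)
  m <- toy_cphmm(exit_prob = 0.02)
  lens <- unlist(replicate(400, sample_unit_lengths(m), simplify = FALSE))
  expect_gt(length(lens), 100)
  tab <- table(lens)
  expect_equal(as.integer(names(tab)[which.max(tab)]), m$base$L)
})

test_that("HMMER3 text profiles are ingested and round-trip", {
  dna <- alphabet("dna")
  # hand-written 2-position file with uniform emissions; the position-1
  # m->m field of 0.0 maps to probability exp(-0) = 1
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c(
    "HMMER3/f [hand-written]",
    "NAME  t", "LENG  2", "ALPH  DNA",
    "HMM          A        C        G        T",
    "           m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    "  COMPO  1.38629  1.38629  1.38629  1.38629",
    "         1.38629  1.38629  1.38629  1.38629",
    "         0.01005  5.29832  5.29832  0.01005  4.60517  0.00000  *",
    "  1      1.38629  1.38629  1.38629  1.38629",
    "         1.38629  1.38629  1.38629  1.38629",
    "         0.00000  *        *        0.01005  4.60517  0.00000  *",
    "  2      1.38629  1.38629  1.38629  1.38629",
    "         1.38629  1.38629  1.38629  1.38629",
    "         0.01005  5.29832  5.29832  0.01005  4.60517  0.00000  *",
    "//"), f)
  p <- read_hmmer_profile(f)
  expect_equal(p$L, 2L)
  expect_equal(unname(p$match_emis[1, ]), rep(0.25, 4), tolerance = 1e-5)
  expect_equal(unname(p$trans[1, "MM"]), 1, tolerance = 1e-9)
  # write(ingest(f)) then ingest again: identical within 1e-6
  f2 <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer_profile(p, f2)
  p2 <- read_hmmer_profile(f2)
  expect_lt(max(abs(p$match_emis - p2$match_emis)), 1e-6)
  expect_lt(max(abs(p$trans - p2$trans)), 1e-6)
  # malformed input names the offending line
  f3 <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c("HMMER3/f", "HMM  A  C  G  T", "  x", "  1  0.1  0.2"), f3)
  expect_error(read_hmmer_profile(f3), "line")
})
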