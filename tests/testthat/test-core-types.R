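test_that("alphabets carry normalized backgrounds and exclude the gap", {
  for (a in list(alphabet("aa"), alphabet("dna"),
                 custom_alphabet(c("A", "B", "C")))) {
    expect_lt(abs(sum(a$background) - 1), 1e-9)
    expect_equal(anyDuplicated(a$symbols), 0L)
    expect_false("-" %in% a$symbols)
  }
  expect_error(custom_alphabet(c("A", "A")), "unique")
  expect_error(custom_alphabet(c("A", "-")), "unique|gap")
})

test_that("sequence records are uppercased and reject gaps", {
  r <- seq_record("s1", "acgt", alphabet("dna"))
  expect_identical(r$residues, "ACGT")
  expect_error(seq_record("s1", "AC-GT"), "gap")
})

test_that("unit_alignment validates rows, spans and parent consistency", {
  aa <- alphabet("aa")
  expect_error(unit_alignment("ACDE", alphabet = aa), ">= 2 units")
  expect_error(unit_alignment(c("ACDE", "ACD"), alphabet = aa),
               "equal length")
  ua <- unit_alignment(c("AC-E", "ACDE"), alphabet = aa,
                       parent_seq = "ACEACDE")
  expect_equal(unname(ua$spans[, "start"]), c(0L, 3L))
  expect_error(unit_alignment(c("AC-E", "ACDE"), alphabet = aa,
                              parent_seq = "ACDACDE"),
               "does not match")
  # overlapping spans rejected
  expect_error(unit_alignment(c("AC", "AC"), alphabet = aa,
                              spans = rbind(c(0, 2), c(1, 3))),
               "non-overlapping")
})

test_that("characteristics reports unit length, divergence and gap runs", {
  aa <- alphabet("aa")
  ch <- characteristics(unit_alignment(c("ACDE", "ACDE"), alphabet = aa))
  expect_equal(ch[c("unit_length", "n_units", "divergence")],
               list(unit_length = 4L, n_units = 2L, divergence = 0))
  expect_equal(ch$indel_counts, c(0L, 0L))
  # divergence = 1 - mean pairwise identity (brute-force value 3/4)
  ch2 <- characteristics(unit_alignment(c("ACDE", "ACDF"), alphabet = aa))
  expect_equal(ch2$divergence, 0.25)
  ch3 <- characteristics(unit_alignment(c("AC-E", "ACDE", "ACDE"),
                                        alphabet = aa))
  expect_equal(ch3$indel_counts, c(1L, 0L, 0L))
  expect_equal(ch3$unit_length, 4L)
})

test_that("divergence is invariant under unit order permutation", {
  aa <- alphabet("aa")
  set.seed(11)
  for (rep in 1:10) {
    rows <- replicate(4, random_protein(8))
    d1 <- characteristics(unit_alignment(rows, alphabet = aa))$divergence
    d2 <- characteristics(unit_alignment(sample(rows), alphabet = aa))$divergence
    expect_equal(d1, d2)
  }
})

test_that("an alignment with no comparable residue pair is degenerate", {
  dna <- alphabet("dna")
  expect_error(characteristics(unit_alignment(c("A-", "-A"), alphabet = dna)),
               "degenerate alignment")
})
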