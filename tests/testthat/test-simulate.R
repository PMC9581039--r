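test_that("zero divergence and no indels copy the ancestral unit", {
  aa <- alphabet("aa")
  sim <- simulate_repeat("ACDEFGHIKL", 4, 0, 0, seed = 1, alphabet = aa)
  expect_identical(sim$truth$units, rep("ACDEFGHIKL", 4))
  # ground-truth spans reconstruct the units from the emitted sequence
  for (u in 1:4)
    expect_identical(substr(sim$record$residues,
                            sim$truth$true_spans[u, 1] + 1L,
                            sim$truth$true_spans[u, 2]),
                     sim$truth$units[u])
})

test_that("the same seed reproduces the simulation exactly", {
  aa <- alphabet("aa")
  s1 <- simulate_repeat("ACDEFGHIKL", 3, 0.2, 0.1, seed = 42, alphabet = aa)
  s2 <- simulate_repeat("ACDEFGHIKL", 3, 0.2, 0.1, seed = 42, alphabet = aa)
  expect_identical(s1$record$residues, s2$record$residues)
  expect_identical(s1$truth$true_spans, s2$truth$true_spans)
  s3 <- simulate_repeat("ACDEFGHIKL", 3, 0.2, 0.1, seed = 43, alphabet = aa)
  expect_false(identical(s1$record$residues, s3$record$residues))
})

test_that("substitutions at small t follow the closed-form p-distance", {
  dna <- alphabet("dna")
  t <- 0.1
  ua <- simulate_unit_alignment(2, 10000, t, alphabet = dna, seed = 77)
  # row 2 differs from the ancestor of row 1 only through both branches;
  # simulate one branch directly instead: mutate the ancestor itself
  sim <- simulate_repeat(paste(rep("ACGT", 2500), collapse = ""), 2, t, 0,
                         flank_lengths = c(0L, 0L), seed = 78,
                         alphabet = dna)
  anc <- strsplit(sim$truth$ancestral_unit, "")[[1]]
  des <- strsplit(sim$truth$units[1], "")[[1]]
  p_obs <- mean(anc != des)
  p_exp <- 3 / 4 * (1 - exp(-4 * t / 3))
  se <- sqrt(p_exp * (1 - p_exp) / length(anc))
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("parameter violations are rejected", {
  aa <- alphabet("aa")
  expect_error(simulate_repeat("ACDE", 1, 0.1, seed = 1, alphabet = aa),
               "n_units")
  expect_error(simulate_repeat("ACDE", 3, -1, seed = 1, alphabet = aa),
               "divergence_t")
  expect_error(simulate_repeat("ACDE", 3, 0.1, 0.5, seed = 1,
                               alphabet = aa), "indel_prob")
})

test_that("benchmarks carry one truth row per sequence", {
  aa <- alphabet("aa")
  b <- make_benchmark(3, 2, "ACDEFGHIKL", seed = 5, alphabet = aa)
  expect_equal(nrow(b$truth), 5)
  expect_equal(sum(b$truth$label == "positive"), 3)
  b0 <- make_benchmark(0, 2, "ACDEFGHIKL", seed = 5, alphabet = aa)
  expect_true(all(b0$truth$label == "negative"))
})

test_that("shuffled negatives preserve residue composition", {
  aa <- alphabet("aa")
  b <- make_benchmark(10, 10, "ACDEFGHIKLMNPQRSTVWY", n_units = 3,
                      divergence_t = 0.1, seed = 17, alphabet = aa)
  comp <- function(recs) {
    ch <- unlist(lapply(recs, function(r)
      strsplit(r$residues, "")[[1]]))
    table(factor(ch, levels = aa$symbols))
  }
  pos <- comp(b$records[b$truth$label == "positive"])
  neg <- comp(b$records[b$truth$label == "negative"])
  expect_gt(suppressWarnings(
    stats::chisq.test(cbind(as.numeric(pos), as.numeric(neg)))$p.value),
    0.01)
})

test_that("perfect planted repeats are always recovered by the search", {
  aa <- alphabet("aa")
  set.seed(61)
  anc <- random_protein(12)
  ua <- unit_alignment(rep(anc, 2), alphabet = aa)
  m <- circularize(build_profile(ua), 0.05)
  found <- 0
  for (i in 1:10) {
    sim <- simulate_repeat(anc, 3, 0, 0, seed = 700 + i, alphabet = aa)
    hits <- viterbi_search(m, sim$record, null_model(aa))
    if (length(hits)) found <- found + 1
  }
  expect_equal(found, 10)
})
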