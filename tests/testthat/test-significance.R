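test_that("the single-column homology statistic matches the closed form", {
  ab <- custom_alphabet(c("A", "B"))
  ua <- unit_alignment(c("A", "A"), alphabet = ab)
  res <- homology_lrt(ua, subst_model_symmetric(ab), null_draws = 0)
  # lnL0 = 2 ln(1/2); lnL1 at t = 0 is ln(1/2); statistic = 2 ln 2
  expect_equal(res$lnL0, 2 * log(0.5), tolerance = 1e-12)
  expect_equal(res$lnL1, log(0.5), tolerance = 1e-12)
  expect_equal(res$statistic, 2 * log(2), tolerance = 1e-9)
  expect_identical(res$t_hat, 0)
})

test_that("identical units give boundary divergence and minimal p-value", {
  aa <- alphabet("aa")
  ua <- unit_alignment(c("ACDEFG", "ACDEFG"), alphabet = aa)
  res <- homology_lrt(ua, null_draws = 99, seed = 3)
  expect_gt(res$statistic, 0)
  expect_identical(res$t_hat, 0)
  expect_lte(res$pvalue, 1 / 100 + 1e-12)
})

test_that("the statistic ignores unit order and never drops when a unit is duplicated", {
  aa <- alphabet("aa")
  set.seed(31)
  for (rep in 1:20) {
    rows <- replicate(3, random_protein(10))
    s1 <- homology_lrt(unit_alignment(rows, alphabet = aa),
                       null_draws = 0)$statistic
    s2 <- homology_lrt(unit_alignment(sample(rows), alphabet = aa),
                       null_draws = 0)$statistic
    expect_equal(s1, s2, tolerance = 1e-7)
    s3 <- homology_lrt(unit_alignment(c(rows, rows[1]), alphabet = aa),
                       null_draws = 0)$statistic
    expect_gte(s3, s1 - 1e-7)
  }
})

test_that("ml_divergence hits the bounds on degenerate inputs", {
  aa <- alphabet("aa")
  expect_identical(ml_divergence(unit_alignment(c("AAAA", "AAAA"),
                                                alphabet = aa)), 0)
  expect_equal(ml_divergence(unit_alignment(c("ACDEFGHIKL", "MNPQRSTVWY"),
                                            alphabet = aa)), 10)
  expect_error(homology_lrt(unit_alignment(c("A-", "-A"),
                                           alphabet = alphabet("dna")),
                            null_draws = 0),
               "degenerate alignment")
})

test_that("divergence is recovered from star-tree simulations", {
  aa <- alphabet("aa")
  for (t in c(0.1, 0.5)) {
    ua <- simulate_unit_alignment(10, 200, t / 2, alphabet = aa,
                                  seed = 400 + round(100 * t))
    expect_lt(abs(ml_divergence(ua) - t) / t, 0.15)
  }
})

test_that("overlap filtering keeps one hit per cluster and is idempotent", {
  base <- data.frame(sequence_id = "s", start = 0, end = 10, n_units = 3,
                     unit_length = 5, viterbi_logodds = 4,
                     forward_logodds = 5, pvalue = 0.01, units = "x",
                     stringsAsFactors = FALSE)
  a <- base
  b <- transform(base, start = 2, pvalue = 0.001, forward_logodds = 4)
  # 80% of the shorter span shared: keep only the lower p-value
  f <- filter_overlaps(rbind(a, b))
  expect_equal(nrow(f), 1)
  expect_equal(f$pvalue, 0.001)
  # disjoint hits both survive
  d <- transform(base, start = 50, end = 60)
  expect_equal(nrow(filter_overlaps(rbind(a, d))), 2)
  # exact duplicates collapse deterministically
  expect_equal(nrow(filter_overlaps(rbind(a, a))), 1)
  # idempotence on a random mix
  set.seed(9)
  mix <- do.call(rbind, lapply(1:12, function(i)
    transform(base, start = sample(0:40, 1),
              end = NA, pvalue = runif(1))))
  mix$end <- mix$start + sample(5:15, 12, TRUE)
  once <- filter_overlaps(mix)
  expect_identical(filter_overlaps(once), once)
})
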