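test_that("indel rates follow the event-count / stationarity estimator", {
  aa <- alphabet("aa")
  # 4 rows with 3 maximal gap runs in total
  rows <- c(a = "ACDEFGHIKLM-", b = "ACDEFGH-KLMN", c = "-CDEFGHIKLMN",
            d = "ACDEFGHIKLMN")
  ua <- unit_alignment(rows, alphabet = aa)
  tree <- ape::read.tree(text = "((a:0.5,b:0.5):0.25,(c:0.25,d:0.5):0);")
  lens <- nchar(gsub("-", "", rows))
  mu_expected <- 3 / (sum(tree$edge.length) * mean(lens))
  est <- estimate_indel_rates(ua, tree)
  expect_equal(unname(est["mu"]), mu_expected, tolerance = 1e-12)
  expect_equal(unname(est["lambda"] / est["mu"]), mean(lens),
               tolerance = 1e-12)
  # gapless initial alignment is rejected, quoting the requirement
  ua0 <- unit_alignment(c(a = "ACDE", b = "ACDE"), alphabet = aa)
  expect_error(estimate_indel_rates(ua0, tree),
               "at least one gap")
})

test_that("guide trees: star below 3 units, NJ recovers additive topology", {
  aa <- alphabet("aa")
  t2 <- infer_guide_tree(unit_alignment(c(x = "ACDE", y = "ACDF"),
                                        alphabet = aa))
  expect_setequal(t2$tip.label, c("x", "y"))
  expect_equal(length(t2$tip.label), 2L)
  # identical units: all distances (and branch lengths) zero
  t3 <- infer_guide_tree(unit_alignment(c(a = "ACDE", b = "ACDE",
                                          c = "ACDE"), alphabet = aa))
  expect_equal(sum(t3$edge.length), 0)
  # additive matrix built by sequence design: (a,b) vs (c,d) split
  rows <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "GGGGGAAAAA",
            d = "GGGGGAAAAC")
  t4 <- infer_guide_tree(unit_alignment(rows, alphabet = aa))
  # the (a,b) cherry must be monophyletic
  mrca <- ape::getMRCA(t4, c("a", "b"))
  expect_setequal(ape::extract.clade(t4, mrca)$tip.label, c("a", "b"))
})

test_that("progressive PIP attains the enumerated pairwise optimum", {
  aa <- alphabet("aa")
  model <- subst_model_symmetric(aa)
  set.seed(99)
  for (trial in 1:8) {
    la <- sample(2:5, 1); lb <- sample(2:5, 1)
    sa <- random_protein(la); sb <- random_protein(lb)
    bx <- runif(1, 0.05, 0.5); by <- runif(1, 0.05, 0.5)
    lambda <- runif(1, 0.2, 2); mu <- runif(1, 0.05, 0.5)
    tree <- ape::read.tree(text = sprintf("(a:%.17g,b:%.17g);", bx, by))
    al <- pip_align(c(a = sa, b = sb), tree = tree,
                    params = pip_params(lambda, mu), model = model,
                    alphabet = aa)
    expect_equal(attr(al, "loglik"),
                 pip_pair_best(sa, sb, bx, by, lambda, mu, model),
                 tolerance = 1e-9)
  }
})

test_that("alignment never loses or reorders residues", {
  aa <- alphabet("aa")
  set.seed(12)
  for (trial in 1:6) {
    n <- sample(2:5, 1)
    units <- stats::setNames(
      vapply(seq_len(n), function(i) random_protein(sample(4:12, 1)),
             character(1)),
      paste0("u", seq_len(n)))
    al <- pip_align(units, params = pip_params(1, 0.1), alphabet = aa)
    expect_identical(gsub("-", "", al$rows[names(units)]), units)
  }
})

test_that("identical units under minimal deletion pressure stack gaplessly", {
  aa <- alphabet("aa")
  al <- pip_align(c(a = "ACDEFG", b = "ACDEFG"),
                  params = pip_params(6e-4, 1e-4), alphabet = aa)
  expect_identical(unname(al$rows), c("ACDEFG", "ACDEFG"))
})

test_that("gamma rate variation converges to constant rates as alpha grows", {
  aa <- alphabet("aa")
  al <- pip_align(c(a = "ACDE", b = "ACE"), params = pip_params(0.5, 0.1),
                  alphabet = aa)
  tree <- ape::read.tree(text = "(a:0.2,b:0.2);")
  ll_c <- pip_loglik(al, tree, pip_params(0.5, 0.1, "constant"))
  ll_g <- pip_loglik(al, tree, pip_params(0.5, 0.1, "gamma", alpha = 1e3))
  expect_equal(ll_c, ll_g, tolerance = 1e-4)
  # and differs materially at the default shape
  ll_g05 <- pip_loglik(al, tree, pip_params(0.5, 0.1, "gamma", alpha = 0.5))
  expect_gt(abs(ll_c - ll_g05), 1e-4)
})

test_that("realign is a fixed point on an already-optimal alignment", {
  aa <- alphabet("aa")
  ua <- unit_alignment(c(a = "AC-EF", b = "ACDEF", c = "ACDEF",
                         d = "ACD-F"), alphabet = aa)
  r1 <- realign_units(ua, "pip")
  r2 <- realign_units(r1, "pip", params = attr(r1, "params"))
  expect_identical(unname(r1$rows), unname(r2$rows))
  # gamma default shape is 0.5
  rg <- realign_units(ua, "pip", rate_model = "gamma")
  expect_equal(attr(rg, "params")$alpha, 0.5)
})

test_that("the MAFFT hook errors clearly when the binary is absent", {
  aa <- alphabet("aa")
  ua <- unit_alignment(c(a = "AC-EF", b = "ACDEF"), alphabet = aa)
  withr::local_envvar(PATH = tempdir())
  expect_error(realign_units(ua, "mafft"), "external tool missing")
})

test_that("pip_params validates its domain", {
  expect_error(pip_params(0, 1), "lambda")
  expect_error(pip_params(1, -1), "mu")
  expect_error(pip_params(1, 1, alpha = 0), "alpha")
  expect_error(pip_align(c(a = "", b = "AC"), alphabet = alphabet("aa")),
               "zero-length")
})
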