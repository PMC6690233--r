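test_that("pruning equals brute-force enumeration over internal states", {
  skip_if_not_installed("Matrix")
  set.seed(17)
  reps <- rep_codes()
  trees <- c(lapply(1:3, function(i) random_quartet_tree()),
             lapply(1:3, function(i) random_quartet_tree(resolved = TRUE)))
  for (tr in trees) for (r in c(0.3, 1, 2.7)) {
    got <- class_likelihood(1:15, tr, r = r)
    want <- vapply(1:15, function(cc)
      oracle_column_lik(reps[cc, ], tr$topology, tr$b, tr$b5, r), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("multiplicity-weighted class likelihoods sum to one", {
  set.seed(23)
  mult <- pattern_classes()$multiplicity
  for (i in 1:4) {
    tr <- random_quartet_tree(resolved = i %% 2 == 0)
    expect_equal(sum(mult * class_likelihood(1:15, tr, r = runif(1, 0, 3))),
                 1, tolerance = 1e-10)
    for (a in c(0.3, 5)) {
      p <- site_pattern_probs(tr, rates = "gamma", alpha = a)
      expect_equal(sum(p), 1, tolerance = 1e-8)
    }
  }
})

test_that("log-likelihoods reproduce published evaluations at fixed parameters", {
  s6 <- c(24, 24, 12, 96, 32)
  # constant rate, star and resolved
  expect_equal(quartet_loglik(c(0, 14, 43, 4, 40),
                              quartet_tree("star", b = 0.426784)),
               -1537.68, tolerance = 1e-5)
  expect_equal(quartet_loglik(s6, quartet_tree("star", b = 1.020276)),
               -2947.793, tolerance = 1e-6)
  expect_equal(quartet_loglik(s6, quartet_tree("12|34",
                                               b = c(0.849814, 0.849814, 1.693866, 0),
                                               b5 = 0.850)),
               -2943.148, tolerance = 1e-6)
  # continuous gamma at the tabulated parameter values
  expect_equal(quartet_loglik(s6, quartet_tree("star", b = 1.020429),
                              rates = "gamma", alpha = 10000),
               -2947.797, tolerance = 1e-6)
  rows <- list(
    list(b = c(2.783640, 1.133961, 1.575337, 2.343977), b5 = 10,
         alpha = 1, lnL = -2930.116),
    list(b = c(3.359848, 1.413517, 1.886961, 2.886549), b5 = 30,
         alpha = 0.843, lnL = -2921.743),
    list(b = c(3.767304, 1.850750, 2.302868, 3.315211), b5 = 50,
         alpha = 0.745, lnL = -2918.782))
  for (row in rows)
    expect_equal(quartet_loglik(s6, quartet_tree("12|34", b = row$b, b5 = row$b5),
                                rates = "gamma", alpha = row$alpha),
                 row$lnL, tolerance = 1e-6)
})

test_that("zero branch lengths give the closed-form monomorphic likelihood", {
  tr0 <- quartet_tree("star", b = 0)
  expect_equal(quartet_loglik(c(0, 0, 0, 0, 400), tr0), 400 * log(0.25))
  expect_equal(class_likelihood(15, tr0), 0.25)
  expect_equal(class_likelihood(1, tr0), 0)   # all-distinct impossible
})

test_that("a resolved tree with b5 = 0 is the star tree", {
  set.seed(31)
  for (i in 1:5) {
    spec <- random_spec()
    b <- runif(4, 0.05, 2)
    star <- quartet_tree("star", b = b)
    for (top in c("12|34", "13|24", "14|23")) {
      res <- quartet_tree(top, b = b, b5 = 0)
      expect_equal(quartet_loglik(spec, res), quartet_loglik(spec, star),
                   tolerance = 1e-12)
    }
  }
})

test_that("the gamma model converges to the constant-rate model as alpha grows", {
  for (spec in list(c(24, 24, 12, 96, 32), c(0, 14, 43, 4, 40))) {
    tr <- quartet_tree("star", b = 1.02)
    expect_equal(quartet_loglik(spec, tr, rates = "gamma", alpha = 1e6),
                 quartet_loglik(spec, tr), tolerance = 1e-3)
  }
})

test_that("fixed-rule and adaptive quadrature agree", {
  s6 <- c(24, 24, 12, 96, 32)
  for (a in c(0.05, 0.745, 1, 100, 1e4)) {
    tr <- quartet_tree("13|24", b = c(0.4, 1.1, 0.7, 2.0), b5 = 0.6)
    expect_equal(quartet_loglik(s6, tr, rates = "gamma", alpha = a),
                 quartet_loglik(s6, tr, rates = "gamma", alpha = a,
                                quadrature = "adaptive"),
                 tolerance = 1e-7)
  }
})

test_that("likelihood of saturating data increases towards the equal-frequency bound", {
  spec <- c(24, 24, 12, 12, 4)           # all 256 patterns once
  bs <- c(0.5, 1, 2, 4, 6)
  ll <- vapply(bs, function(b)
    quartet_loglik(spec, quartet_tree("star", b = b)), numeric(1))
  expect_true(all(diff(ll) > 0))
  # every column likelihood tends to 1/256 at saturation, so the supremum
  # of lnL for 256 sites is 256 * log(1/256), approached from below
  expect_true(all(ll < 256 * log(1 / 256)))
  expect_equal(quartet_loglik(spec, quartet_tree("star", b = 10)),
               256 * log(1 / 256), tolerance = 1e-6)
})

test_that("expected pattern probabilities hit their degenerate and saturated limits", {
  p0 <- site_pattern_probs(quartet_tree("star", b = 0))
  expect_equal(unname(p0[15]), 1)
  expect_equal(sum(p0), 1)
  psat <- site_pattern_probs(quartet_tree("star", b = 50))
  expect_equal(unname(psat), pattern_classes()$multiplicity / 256,
               tolerance = 1e-8)
})

test_that("constant-rate likelihood matches an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  spec <- c(10, 6, 9, 3, 25)
  aln <- quartet_alignment(spec)
  tr <- quartet_tree("12|34", b = c(0.3, 0.5, 0.8, 0.2), b5 = 0.4)
  fitref <- phangorn::pml(as.phylo(tr), phangorn::phyDat(tolower(aln), type = "DNA"),
                          model = "JC")
  expect_equal(quartet_loglik(spec, tr), as.numeric(fitref$logLik),
               tolerance = 1e-8)
})
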