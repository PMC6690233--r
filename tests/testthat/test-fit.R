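test_that("star fits of star-simulated pattern sets recover the published estimates", {
  a <- quartet_ml(c(0, 14, 43, 4, 40))
  expect_equal(unname(coef(a)), rep(0.426784, 4), tolerance = 1e-4)
  expect_equal(a$logLik, -1537.68, tolerance = 1e-5)
  expect_true(a$converged)

  b <- quartet_ml(c(1, 11, 41, 5, 42))
  expect_equal(unname(coef(b)), rep(0.400584, 4), tolerance = 1e-4)
  expect_equal(b$logLik, -1416.09, tolerance = 1e-5)
})

test_that("fully saturated data is fit at the branch cap, star and resolved alike", {
  spec <- c(24, 24, 12, 12, 4)
  star10 <- quartet_ml(spec, "star", b_max = 10)
  expect_equal(star10$logLik, -1419.57, tolerance = 1e-5)
  res10 <- quartet_ml(spec, "12|34", b_max = 10)
  expect_equal(res10$logLik, star10$logLik, tolerance = 1e-4)
  # raising the cap moves the branches but keeps star = resolved parity
  star100 <- quartet_ml(spec, "star", b_max = 100)
  res100 <- quartet_ml(spec, "12|34", b_max = 100)
  expect_gt(max(coef(star100)), max(coef(star10)) + 1)
  # lnL at cap 10 already sits within ~1e-7 of the 256 * ln(1/256) bound,
  # so raising the cap must not lower it
  expect_gte(star100$logLik, star10$logLik - 1e-6)
  expect_equal(res100$logLik, star100$logLik, tolerance = 1e-4)
})

test_that("monomorphic data drives every branch to the lower bound", {
  f <- quartet_ml(c(0, 0, 0, 0, 100), "13|24")
  expect_equal(unname(coef(f)), rep(0, 5), tolerance = 1e-6)
  expect_equal(f$logLik, 100 * log(0.25))
  expect_true(f$bound_hits[["b_min"]])
})

test_that("fits are deterministic and report consistent bound hits", {
  f1 <- quartet_ml(c(24, 24, 12, 96, 32), rates = "gamma")
  f2 <- quartet_ml(c(24, 24, 12, 96, 32), rates = "gamma")
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$logLik, f2$logLik)
  expect_true(f1$bound_hits[["alpha_max"]])   # no detectable heterogeneity
  expect_equal(unname(coef(f1)["alpha"]), 1e4)
  expect_equal(f1$logLik, -2947.797, tolerance = 1e-5)
})

test_that("the gamma star fit reproduces the two long published fits", {
  f <- quartet_ml(c(168, 216, 156, 120, 80), rates = "gamma",
                  alpha_max = 5000)
  expect_equal(f$logLik, -13965.18, tolerance = 1e-5)
  expect_equal(unname(coef(f)[1:4]), rep(1.118709, 4), tolerance = 1e-3)
  expect_true(f$bound_hits[["alpha_max"]])

  g <- quartet_ml(c(120, 192, 120, 204, 164), rates = "gamma")
  expect_equal(g$logLik, -13889.49, tolerance = 1e-5)
})

test_that("profiling the internal branch matches the star fit at b5 = 0 and rises with b5", {
  spec <- c(24, 24, 12, 96, 32)
  prof <- profile_internal_branch(spec, "12|34", rates = "gamma",
                                  b5 = c(0, 10, 30, 50), b_max = 50)
  star <- quartet_ml(spec, "star", rates = "gamma")
  expect_equal(prof$lnL[1], star$logLik, tolerance = 1e-4)
  expect_true(all(diff(prof$lnL) > 0))
  # the b5 = 10 profile point: the published parameter vector evaluates to
  # -2930.116 (checked against the likelihood directly), and the profile
  # maximum sits slightly above it on the same ridge
  expect_gt(prof$lnL[2], -2930.116)
  expect_lt(prof$lnL[2], -2929)
  expect_equal(prof$alpha[2], 1.16, tolerance = 0.05)
  expect_equal(prof$lnL[4], -2918.78, tolerance = 1e-3)
  expect_equal(prof$alpha[4], 0.745, tolerance = 1e-2)
})

test_that("user-supplied extra starts can reach asymmetric star optima", {
  # for this G4-enriched combination the star surface has an asymmetric
  # maximum above the symmetric stationary point found by the default grid
  spec <- c(24, 24, 12, 96, 32)
  sym <- quartet_ml(spec, "star")
  asym <- quartet_ml(spec, "star",
                     control = list(extra_starts = list(c(1.7, 0, 1.7, 1.7))))
  expect_equal(sym$logLik, -2947.793, tolerance = 1e-5)
  expect_equal(asym$logLik, -2947.435, tolerance = 1e-3)
  expect_gt(asym$logLik, sym$logLik)
})

test_that("star parameters are recovered from star-simulated data", {
  sim <- simulate_quartet(quartet_tree("star", b = 0.3), nsites = 5000,
                          nsim = 1, seed = 99)[[1]]
  fit <- quartet_ml(sim, "star")
  # binomial-scale Monte-Carlo error on a branch of length .3 at n = 5000
  expect_equal(unname(coef(fit)), rep(0.3, 4), tolerance = 0.1)
  lrt <- star_test(sim)
  expect_lt(lrt$resolved[[1]]$tree$b5, 0.02)
})

test_that("model comparison via anova matches the likelihood-ratio arithmetic", {
  spec <- c(24, 24, 12, 96, 32)
  star <- quartet_ml(spec, "star")
  res <- quartet_ml(spec, "12|34")
  tab <- anova(star, res)
  expect_equal(tab$statistic[2], 2 * (res$logLik - star$logLik))
  expect_equal(tab$Df[2], 1)
  expect_equal(tab$p.value[2],
               pchisq(tab$statistic[2], 1, lower.tail = FALSE))
  expect_error(anova(star, quartet_ml(c(1, 1, 1, 1, 1), "star")),
               "same pattern counts")
})

test_that("fitted objects expose the standard accessor methods", {
  fit <- quartet_ml(c(0, 14, 43, 4, 40))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 4)
  expect_equal(attr(ll, "nobs"), 308)
  expect_equal(sum(predict(fit, "probs")), 1, tolerance = 1e-9)
  expect_equal(sum(predict(fit, "counts")), 308, tolerance = 1e-6)
  r <- residuals(fit)
  expect_length(r, 15)
  expect_lt(max(abs(r)), 5)        # star-simulated data fits its own model
  s <- summary(fit)
  expect_true(s$equidistant)
  expect_output(print(fit), "star")
  expect_output(print(s), "equidistant")
})
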