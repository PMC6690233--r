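# Star-vs-resolved likelihood-ratio test and the site-pattern
# goodness-of-fit check for "no tree model fits" situations.

#' Likelihood-ratio test of the star tree against the best resolved tree
#'
#' Fits the star tree and all three resolved pairings, takes the best
#' resolved fit (ties broken in the fixed order 12|34, 13|24, 14|23) and
#' computes `2dlnL = 2 (lnL_resolved - lnL_star)` with an upper-tail
#' chi-square p-value on 1 degree of freedom.  Each resolved fit is
#' warm-started from the star solution (its `b5 = 0` nesting point) in
#' addition to the standard restart grid, which guarantees
#' `lnL_resolved >= lnL_star`; a negative statistic within numerical
#' tolerance is clamped to 0.
#'
#' The plain chi-square(1) reference reproduces the test as customarily
#' applied, even though the null pins `b5` to the boundary of its range,
#' where the textbook reference is the 50:50 mixture of chi-square(0) and
#' chi-square(1); set `boundary_mix = TRUE` for the mixture (which halves
#' the p-value for a positive statistic).
#'
#' @inheritParams quartet_ml
#' @param boundary_mix Use the boundary-corrected 50:50 mixture reference
#'   distribution instead of plain chi-square(1).
#' @return An object of class `star_lrt`: a list with the star fit, the
#'   three resolved fits, `best_topology`, `lnL_star`, `lnL_resolved`,
#'   `statistic`, `df` and `p.value`.
#' @examples
#' \donttest{
#' star_test(c(24, 24, 12, 96, 32))   # 2dlnL = 9.29, p = 0.0023
#' star_test(c(0, 14, 43, 4, 40))     # statistic ~ 0: star retained
#' }
#' @export
star_test <- function(x, rates = c("constant", "gamma"),
                      b_max = 10, b_min = 0,
                      alpha_max = 1e4, alpha_min = 1e-3,
                      boundary_mix = FALSE, control = list()) {
  counts <- as_pattern_counts(x)
  rates <- match.arg(rates)
  star <- quartet_ml(counts, "star", rates = rates, b_max = b_max,
                     b_min = b_min, alpha_max = alpha_max,
                     alpha_min = alpha_min, control = control)
  warm <- list(b = star$tree$b, b5 = max(b_min, 0),
               alpha = star$alpha)
  resolved <- lapply(c("12|34", "13|24", "14|23"), function(top) {
    fit <- .fit_quartet(counts, top, rates, b5_fix = NULL,
                        b_min = b_min, b_max = b_max,
                        alpha_min = alpha_min, alpha_max = alpha_max,
                        warm = warm, control = control)
    fit$counts <- counts
    fit$df <- 5L + (rates == "gamma")
    fit$nobs <- sum(counts)
    class(fit) <- "quartet_ml"
    fit
  })
  lls <- vapply(resolved, `[[`, numeric(1L), "logLik")
  best <- which.max(lls)              # which.max takes the first of ties
  stat <- 2 * (lls[best] - star$logLik)
  if (stat < -1e-6)
    warning("resolved fit below the nested star fit by more than tolerance")
  stat <- max(stat, 0)
  p <- if (stat <= 0) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary_mix) p <- if (stat <= 0) 1 else 0.5 * p
  structure(list(star = star, resolved = resolved,
                 best_topology = c("12|34", "13|24", "14|23")[best],
                 lnL_star = star$logLik, lnL_resolved = lls[best],
                 statistic = stat, df = 1L, p.value = p,
                 boundary_mix = boundary_mix, rates = rates),
            class = "star_lrt")
}

#' @export
print.star_lrt <- function(x, ...) {
  cat("Star-tree likelihood-ratio test (JC69",
      if (x$rates == "gamma") " + continuous gamma rates" else ", constant rate",
      ")\n", sep = "")
  cat("  lnL star tree:     ", format(x$lnL_star, nsmall = 3), "\n")
  cat("  lnL best resolved: ", format(x$lnL_resolved, nsmall = 3),
      "  [", x$best_topology, "]\n", sep = "")
  cat("  2dlnL = ", format(x$statistic, digits = 5), ",  df = ", x$df,
      ",  p = ", format.pval(x$p.value, digits = 3),
      if (x$boundary_mix) "  (boundary-corrected mixture)", "\n", sep = "")
  cat("  ", if (x$p.value < 0.05) "star tree rejected"
      else "star tree not rejected", " at the 5% level\n", sep = "")
  invisible(x)
}

#' Site-pattern goodness-of-fit test for a fitted tree + model
#'
#' Given a tree and substitution model fitted to a set of sequences, the
#' empirical site-pattern class counts can be compared against their
#' expectation under that tree and model.  A significant deviation means
#' no single tree model fits the data (for instance a concatenation of
#' sequences with different evolutionary histories).  The statistic is the
#' likelihood-ratio G statistic over the 15 classes,
#' `G = 2 sum O_c ln(O_c / E_c)` (classes with `O_c = 0` contribute 0),
#' and significance is assessed by parametric bootstrap: `n_boot`
#' multinomial draws from the expected class probabilities, each refitted
#' under the same topology, rate model and bounds.
#'
#' @param object A [quartet_ml()] fit (fitted to the observed counts).
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap draws.
#' @return An object of class `pattern_gof`: observed and expected counts,
#'   `statistic`, `p.value` (the fraction of bootstrap statistics at or
#'   above the observed one), `n_boot` and the bootstrap statistics.
#' @examples
#' \donttest{
#' fit <- quartet_ml(c(24, 24, 12, 96, 32))
#' pattern_gof(fit, n_boot = 99, seed = 1)  # no tree model fits: small p
#' }
#' @export
pattern_gof <- function(object, n_boot = 200, seed = 1) {
  if (!inherits(object, "quartet_ml"))
    stop("object must be a quartet_ml fit", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  n <- sum(object$counts)
  probs <- predict(object, "probs")
  expected <- n * probs
  gstat <- function(o, e) {
    i <- o > 0
    if (any(e[i] <= 0)) return(Inf)
    2 * sum(o[i] * log(o[i] / e[i]))
  }
  g_obs <- gstat(as.numeric(object$counts), expected)

  warm <- list(b = object$tree$b,
               b5 = if (object$topology == "star") NULL else object$tree$b5,
               alpha = object$alpha)
  b5_fix <- if (object$b5_fixed) object$tree$b5 else NULL
  set.seed(seed)
  g_boot <- vapply(seq_len(n_boot), function(i) {
    sim <- as.numeric(stats::rmultinom(1L, n, probs))
    refit <- .fit_quartet(sim, object$topology, object$rates,
                          b5_fix = b5_fix,
                          b_min = object$bounds$b_min,
                          b_max = object$bounds$b_max,
                          alpha_min = object$bounds$alpha_min,
                          alpha_max = object$bounds$alpha_max,
                          starts = "warm", warm = warm)
    gstat(sim, sum(sim) * site_pattern_probs(refit$tree, refit$rates,
                                             refit$alpha))
  }, numeric(1L))
  p <- mean(g_boot >= g_obs)
  structure(list(observed = as.numeric(object$counts), expected = expected,
                 statistic = g_obs, p.value = p, n_boot = n_boot,
                 boot_stats = g_boot, seed = seed,
                 infinite_g = !is.finite(g_obs)),
            class = "pattern_gof")
}

#' @export
print.pattern_gof <- function(x, ...) {
  cat("Site-pattern goodness-of-fit (parametric bootstrap, G statistic)\n")
  cat("  G = ", format(x$statistic, digits = 6), ",  bootstrap p ",
      if (x$p.value == 0) paste0("< ", format(1 / x$n_boot, digits = 2))
      else paste0("= ", format(x$p.value, digits = 3)),
      "  (", x$n_boot, " replicates)\n", sep = "")
  if (x$infinite_g)
    cat("  note: an observed class has zero expected probability (G infinite)\n")
  cat("  ", if (x$p.value < 0.05)
    "site patterns deviate significantly from the fitted tree model"
    else "no significant deviation from the fitted tree model", "\n", sep = "")
  invisible(x)
}
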