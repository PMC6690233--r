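# Bounded maximum-likelihood estimation of quartet branch lengths (and the
# gamma shape) by L-BFGS-B over a deterministic grid of restarts.
#
# The likelihood surface of the resolved topologies is ridged: for
# within-group-equal pattern counts the optimum is typically a ridge of
# parameter vectors with identical lnL (e.g. one terminal branch absorbed
# into the internal branch), and a quasi-Newton run from a cherry-symmetric
# start stays cherry-symmetric forever (the gradient preserves the
# symmetry), stalling below the ridge.  Resolved topologies therefore add
# two "stretched cherry" asymmetric starts to the symmetric grid; the star
# topology keeps the purely symmetric grid (see the vignette for what this
# implies on pathological G4-enriched data, and control$extra_starts for
# chasing asymmetric star optima).  Gamma fits cross the branch starts with
# shape starts {1, 1000} because the surface has a saturated local optimum
# (long branches, small alpha) separated from the near-homogeneous one.

.fit_control <- function(control = list()) {
  ctl <- list(factr = 1e4, maxit = 500L, quadrature = "gauss",
              bound_tol = 1e-5, extra_starts = list())
  ctl[names(control)] <- control
  ctl
}

.start_branch <- function(counts, b_min, b_max) {
  n <- sum(counts)
  p <- mean(pairwise_differences(counts)) / n
  b0 <- if (p >= 0.7499) 0.9 * b_max else jc69_distance(p) / 2
  min(max(b0, b_min + 1e-4), 0.95 * b_max)
}

.fit_quartet <- function(counts, topology, rates, b5_fix = NULL,
                         b_min = 0, b_max = 10,
                         alpha_min = 1e-3, alpha_max = 1e4,
                         starts = c("full", "warm"), warm = NULL,
                         control = list()) {
  ctl <- .fit_control(control)
  starts <- match.arg(starts)
  cvec <- as.numeric(counts)
  gamma <- rates == "gamma"
  free5 <- topology != "star" && is.null(b5_fix)
  nb <- 4L + free5
  b5_struct <- if (topology == "star") 0 else b5_fix   # NULL when free

  b0 <- .start_branch(counts, b_min, b_max)
  lo <- max(0.1 * b_max, b_min)
  hi <- 0.9 * b_max
  branch_starts <- list(rep(b0, 4L), rep(lo, 4L), rep(hi, 4L))
  if (topology != "star") {          # stretched-cherry starts for the ridge
    stretch <- min(2 * b0, hi)
    branch_starts <- c(branch_starts,
                       list(c(b0, b0, stretch, b_min),
                            c(stretch, b_min, b0, b0)))
  }
  if (free5) {
    b5s <- c(b0, lo, hi, b0, b0)
    branch_starts <- Map(c, branch_starts, b5s)
    branch_starts <- c(branch_starts, list(c(rep(b0, 4L), b_min + 0.01)))
  }
  if (starts == "warm") branch_starts <- branch_starts[1L]
  if (!is.null(warm)) {
    wb <- warm$b
    if (free5) wb <- c(wb, warm$b5)
    branch_starts <- c(list(pmin(pmax(wb, b_min), b_max)), branch_starts)
  }
  alpha_starts <- if (!gamma) NA_real_ else {
    a <- unique(pmin(pmax(c(1, 1000), alpha_min), alpha_max))
    if (!is.null(warm) && !is.null(warm$alpha))
      a <- unique(c(pmin(pmax(warm$alpha, alpha_min), alpha_max), a))
    a
  }
  np_free <- nb + gamma
  extra <- lapply(ctl$extra_starts, function(s) {
    s <- as.numeric(s)
    if (!length(s) %in% c(np_free - gamma, np_free))
      stop("each extra start must supply the ", nb, " free branch lengths",
           if (gamma) " (optionally followed by alpha)", call. = FALSE)
    s
  })

  objective <- function(p) {
    b <- p[1:4]
    b5 <- if (free5) p[5L] else b5_struct
    L <- if (gamma) {
      .class_lik_gamma(b, b5, topology, exp(p[length(p)]), ctl$quadrature)
    } else {
      .class_lik(b, b5, topology, 1)[1L, ]
    }
    -sum(cvec * .safe_log(L))
  }

  lower <- rep(b_min, nb); upper <- rep(b_max, nb)
  if (gamma) { lower <- c(lower, log(alpha_min)); upper <- c(upper, log(alpha_max)) }

  start_points <- list()
  for (bs in branch_starts) for (a0 in alpha_starts)
    start_points[[length(start_points) + 1L]] <-
      if (gamma) c(bs, log(a0)) else bs
  for (s in extra)
    start_points[[length(start_points) + 1L]] <- {
      b_part <- pmin(pmax(s[seq_len(nb)], b_min), b_max)
      if (gamma) {
        a0 <- if (length(s) == np_free) s[np_free] else 1
        c(b_part, log(min(max(a0, alpha_min), alpha_max)))
      } else b_part
    }

  best <- NULL
  restart_values <- numeric(0)
  any_converged <- FALSE
  for (p0 in start_points) {
    o <- tryCatch(
      stats::optim(p0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = ctl$factr, maxit = ctl$maxit)),
      error = function(e) NULL)
    if (is.null(o)) next
    restart_values <- c(restart_values, -o$value)
    if (o$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("optimization failed from every restart", call. = FALSE)

  b_hat <- pmin(pmax(best$par[1:4], b_min), b_max)
  b5_hat <- if (free5) min(max(best$par[5L], b_min), b_max) else b5_struct
  alpha_hat <- if (gamma) exp(best$par[length(best$par)]) else NULL

  tol <- ctl$bound_tol * max(1, b_max)
  bh <- c(b_min = any(abs(c(b_hat, if (free5) b5_hat) - b_min) < tol),
          b_max = any(abs(c(b_hat, if (free5) b5_hat) - b_max) < tol),
          alpha_min = gamma && abs(log(alpha_hat) - log(alpha_min)) < 1e-4,
          alpha_max = gamma && abs(log(alpha_hat) - log(alpha_max)) < 1e-4)

  list(topology = topology, rates = rates,
       tree = quartet_tree(topology, b = b_hat,
                           b5 = if (topology == "star") 0 else b5_hat),
       alpha = alpha_hat, b5_fixed = !is.null(b5_fix),
       logLik = -best$value, bound_hits = bh,
       converged = best$convergence == 0L && any_converged,
       n_restarts = length(restart_values),
       restart_values = restart_values,
       bounds = list(b_min = b_min, b_max = b_max,
                     alpha_min = alpha_min, alpha_max = alpha_max))
}

#' Maximum-likelihood fit of a quartet tree under JC69
#'
#' Maximizes the JC69 log-likelihood of four-sequence site-pattern counts
#' over the branch lengths of a star or resolved quartet topology, under a
#' constant rate or continuous gamma-distributed rate heterogeneity (shape
#' `alpha` estimated on a log scale, rate integral by quadrature).
#' Optimization is bounded L-BFGS-B from a fixed deterministic grid of
#' restarts, so two runs with identical inputs give identical results.
#' The grid uses three symmetric starts (a distance-based guess and 0.1 /
#' 0.9 of `b_max`); resolved topologies add two "stretched cherry"
#' asymmetric starts because their likelihood surface is ridged along
#' cherry asymmetries; gamma fits cross all branch starts with shape
#' starts 1 and 1000.  See the package vignette for the multiple-optima
#' behaviour of pathological pattern combinations and
#' `control$extra_starts` for supplying further start points.
#'
#' Branch-length upper bounds matter for saturated data: lnL changes very
#' little beyond length ~10, so the fit reports which estimates sit at a
#' bound.  An estimated `alpha` at `alpha_max` means no detectable rate
#' heterogeneity.
#'
#' @param x The data: a `pattern_counts` object, a length-5 `(n1..n5)`
#'   spec, a length-15 count vector, or a 4-row alignment matrix.
#' @param topology `"star"` (default) or one of `"12|34"`, `"13|24"`,
#'   `"14|23"`.  The star tree has 4 free branch lengths; a resolved tree
#'   has 5 unless `b5` is fixed.
#' @param rates `"constant"` or `"gamma"`.
#' @param b_max,b_min Branch-length bounds (defaults 10 and 0).
#' @param alpha_max,alpha_min Gamma-shape bounds (defaults 10000 and 1e-3).
#' @param b5 Optional fixed value for the internal branch of a resolved
#'   topology (profile fit over `b1..b4` and `alpha`).
#' @param control Optional list overriding optimizer settings: `factr`,
#'   `maxit` (passed to [stats::optim()]), `quadrature` (`"gauss"` or
#'   `"adaptive"`), and `extra_starts`, a list of additional start points
#'   (each the free branch lengths, optionally followed by a shape value
#'   for gamma fits) appended to the built-in restart grid.
#' @return An object of class `quartet_ml` with `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `residuals`, `simulate`, `plot` and
#'   `anova` methods.
#' @examples
#' fit <- quartet_ml(c(0, 14, 43, 4, 40))          # star, constant rate
#' coef(fit)                                       # all branches 0.426784
#' logLik(fit)                                     # -1537.68
#' \donttest{
#' quartet_ml(c(24, 24, 12, 96, 32), rates = "gamma")  # alpha at the cap
#' }
#' @seealso [star_test()] for the star-vs-resolved likelihood-ratio test,
#'   [profile_internal_branch()] for profiling over fixed `b5`,
#'   [pattern_gof()] for the site-pattern goodness-of-fit test.
#' @export
quartet_ml <- function(x, topology = c("star", "12|34", "13|24", "14|23"),
                       rates = c("constant", "gamma"),
                       b_max = 10, b_min = 0,
                       alpha_max = 1e4, alpha_min = 1e-3,
                       b5 = NULL, control = list()) {
  counts <- as_pattern_counts(x)
  topology <- match.arg(topology)
  rates <- match.arg(rates)
  if (b_min < 0 || b_max <= b_min) stop("need 0 <= b_min < b_max", call. = FALSE)
  if (alpha_min <= 0 || alpha_max <= alpha_min)
    stop("need 0 < alpha_min < alpha_max", call. = FALSE)
  if (!is.null(b5)) {
    if (topology == "star")
      stop("b5 is structurally 0 for the star tree and cannot be fixed",
           call. = FALSE)
    if (length(b5) != 1L || b5 < 0)
      stop("b5 must be a single non-negative value", call. = FALSE)
  }
  fit <- .fit_quartet(counts, topology, rates, b5_fix = b5,
                      b_min = b_min, b_max = b_max,
                      alpha_min = alpha_min, alpha_max = alpha_max,
                      control = control)
  fit$counts <- counts
  fit$df <- 4L + (topology != "star" && is.null(b5)) + (rates == "gamma")
  fit$nobs <- sum(counts)
  fit$call <- match.call()
  class(fit) <- "quartet_ml"
  fit
}

#' @export
print.quartet_ml <- function(x, digits = 6, ...) {
  cat("Quartet maximum-likelihood fit (JC69",
      if (x$rates == "gamma") " + continuous gamma rates" else ", constant rate",
      ")\n", sep = "")
  cat("Topology: ", x$topology,
      if (x$b5_fixed) paste0("  (b5 fixed at ", format(x$tree$b5), ")"),
      "\n", sep = "")
  print(round(coef(x), digits))
  cat("log-likelihood: ", format(x$logLik, nsmall = 3), "  (",
      sum(x$counts), " sites, ", x$df, " free parameters)\n", sep = "")
  if (x$bound_hits[["b_max"]])
    cat("note: branch length estimate(s) at the upper bound b_max =",
        x$bounds$b_max, "\n")
  if (isTRUE(x$bound_hits[["alpha_max"]]))
    cat("note: alpha at the upper bound (", x$bounds$alpha_max,
        "): no detectable rate heterogeneity\n", sep = "")
  if (isTRUE(x$bound_hits[["alpha_min"]]))
    cat("note: alpha at the lower bound", x$bounds$alpha_min, "\n")
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.quartet_ml <- function(object, ...) {
  out <- object$tree$b
  names(out) <- paste0("b", 1:4)
  if (object$topology != "star") out <- c(out, b5 = object$tree$b5)
  if (object$rates == "gamma") out <- c(out, alpha = object$alpha)
  out
}

#' @export
logLik.quartet_ml <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' Expected site-pattern probabilities or counts from a fitted quartet
#'
#' @param object A [quartet_ml()] fit.
#' @param type `"probs"` for class probabilities, `"counts"` for expected
#'   counts at the fitted alignment length.
#' @param ... Ignored.
#' @return Named numeric vector of length 15.
#' @export
predict.quartet_ml <- function(object, type = c("probs", "counts"), ...) {
  type <- match.arg(type)
  p <- site_pattern_probs(object$tree, rates = object$rates,
                          alpha = object$alpha)
  if (type == "counts") p * sum(object$counts) else p
}

#' @export
residuals.quartet_ml <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  e <- predict(object, "counts")
  o <- as.numeric(object$counts)
  r <- if (type == "pearson") (o - e) / sqrt(pmax(e, .Machine$double.eps)) else o - e
  names(r) <- .CLASS_LABELS
  r
}

#' @export
summary.quartet_ml <- function(object, ...) {
  pd <- pairwise_differences(object$counts)
  out <- list(
    fit = object,
    coefficients = coef(object),
    observed = as.numeric(object$counts),
    expected = predict(object, "counts"),
    pearson = residuals(object, "pearson"),
    equidistant = length(unique(pd)) == 1L,
    pairwise_p = pd / sum(object$counts))
  class(out) <- "summary.quartet_ml"
  out
}

#' @export
print.summary.quartet_ml <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nSequences equidistant:", if (x$equidistant) "yes" else "no",
      " (pairwise difference proportions ",
      paste(round(range(x$pairwise_p), 4), collapse = " .. "), ")\n", sep = "")
  tab <- data.frame(class = .CLASS_LABELS,
                    observed = x$observed,
                    expected = round(x$expected, 2),
                    pearson = round(x$pearson, 2))
  cat("\nObserved vs expected site-pattern counts:\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.quartet_ml <- function(x, ...) {
  o <- as.numeric(x$counts)
  e <- predict(x, "counts")
  m <- rbind(observed = o, expected = e)
  colnames(m) <- .CLASS_LABELS
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = c("observed", "expected"),
                    ylab = "sites", ...)
  invisible(x)
}

#' Likelihood-ratio comparison of nested quartet fits
#'
#' Compares two fits of the *same* pattern counts (e.g. star vs resolved,
#' or constant vs gamma rates) by the chi-square likelihood-ratio test on
#' the difference in free parameters.
#'
#' @param object,... Two `quartet_ml` fits, the smaller model first.
#' @return An `anova`-style data frame.
#' @export
anova.quartet_ml <- function(object, ...) {
  others <- list(...)
  if (length(others) != 1L || !inherits(others[[1L]], "quartet_ml"))
    stop("supply exactly two quartet_ml fits", call. = FALSE)
  fit2 <- others[[1L]]
  if (!isTRUE(all.equal(as.numeric(object$counts), as.numeric(fit2$counts))))
    stop("the two fits must be of the same pattern counts", call. = FALSE)
  if (fit2$df < object$df) { tmp <- object; object <- fit2; fit2 <- tmp }
  stat <- max(2 * (fit2$logLik - object$logLik), 0)
  df <- fit2$df - object$df
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  structure(
    data.frame(df = c(object$df, fit2$df),
               logLik = c(object$logLik, fit2$logLik),
               statistic = c(NA, stat), Df = c(NA, df), p.value = c(NA, p)),
    heading = "Likelihood-ratio comparison of quartet fits",
    class = c("anova", "data.frame"))
}

#' Profile the likelihood over fixed internal branch lengths
#'
#' For each value of `b5`, maximizes the log-likelihood of a resolved
#' topology over the four terminal branches (and `alpha` under the gamma
#' model) with the internal branch held fixed.  With `b5 = 0` the fit is
#' identical to the star-tree fit.
#'
#' @inheritParams quartet_ml
#' @param b5 Vector of internal branch lengths to profile over.
#' @return A data frame with one row per `b5` value (columns `b5`, `lnL`,
#'   `b1..b4`, `alpha`, `converged`); the full fits are in
#'   `attr(, "fits")`.
#' @examples
#' \donttest{
#' profile_internal_branch(c(24, 24, 12, 96, 32), rates = "gamma",
#'                         b5 = c(10, 30, 50), b_max = 50)
#' }
#' @export
profile_internal_branch <- function(x, topology = c("12|34", "13|24", "14|23"),
                                    rates = c("constant", "gamma"),
                                    b5, b_max = 10, b_min = 0,
                                    alpha_max = 1e4, alpha_min = 1e-3,
                                    control = list()) {
  topology <- match.arg(topology)
  rates <- match.arg(rates)
  fits <- lapply(b5, function(v)
    quartet_ml(x, topology = topology, rates = rates, b5 = v,
               b_max = b_max, b_min = b_min,
               alpha_max = alpha_max, alpha_min = alpha_min,
               control = control))
  out <- data.frame(
    b5 = b5,
    lnL = vapply(fits, `[[`, numeric(1L), "logLik"),
    t(vapply(fits, function(f) f$tree$b, numeric(4L))),
    alpha = if (rates == "gamma")
      vapply(fits, `[[`, numeric(1L), "alpha") else NA_real_,
    converged = vapply(fits, `[[`, logical(1L), "converged"))
  names(out)[3:6] <- paste0("b", 1:4)
  attr(out, "fits") <- fits
  out
}
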