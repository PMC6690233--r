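# Sequence-evolution simulation under JC69 on a quartet, and the sweep of
# the star-tree likelihood-ratio statistic against the excess of
# parsimony-informative (G4) over 3+1 (G3) site patterns.

.evolve_branch <- function(parent, d, r) {
  # exact per-branch transition sampling: stay with prob 1/4 + 3/4 e^{-4rd/3},
  # otherwise move uniformly to one of the other three nucleotides
  ps <- 0.25 + 0.75 * exp(-4 * r * d / 3)
  n <- length(parent)
  child <- parent
  move <- stats::runif(n) >= ps
  k <- sum(move)
  if (k > 0) {
    offset <- sample.int(3L, k, replace = TRUE)
    child[move] <- ((parent[move] - 1L + offset) %% 4L) + 1L
  }
  child
}

#' Simulate quartet sequence evolution under JC69
#'
#' Evolves each site independently: the root state is drawn uniformly; if
#' `rates = "gamma"` a per-site rate multiplier is drawn from the mean-1
#' gamma distribution with shape `alpha`; each branch then applies the
#' JC69 transition probabilities at length `r * b`.  On a resolved
#' topology the two internal nodes are linked by the internal branch `b5`.
#' Per-branch transition sampling is exact under JC69 (no event-level
#' simulation needed).
#'
#' Replicate `i` is generated under seed `seed + i`, so individual
#' replicates are reproducible in isolation.
#'
#' @param tree A [quartet_tree()] to simulate along.
#' @param rates `"constant"` or `"gamma"`.
#' @param alpha Gamma shape (required when `rates = "gamma"`).
#' @param nsites Alignment length.
#' @param nsim Number of replicate alignments.
#' @param seed Integer base seed (mandatory for reproducibility).
#' @param symmetrize Equalize pattern counts within each of G2, G3, G4
#'   ([symmetrize_counts()] with `trim = TRUE`, so a few remainder sites
#'   may be dropped).  Only available with `output = "counts"`.
#' @param output `"counts"` (list of `pattern_counts`) or `"alignment"`
#'   (list of 4 x L character matrices).
#' @return A list of length `nsim`.
#' @examples
#' sims <- simulate_quartet(quartet_tree("star", b = 1.2),
#'                          nsites = 2528, nsim = 3, seed = 42)
#' sapply(sims, pattern_spec)   # close to (168, 216, 156, 120, 80)
#' @export
simulate_quartet <- function(tree, rates = c("constant", "gamma"),
                             alpha = NULL, nsites, nsim = 1, seed,
                             symmetrize = FALSE,
                             output = c("counts", "alignment")) {
  tree <- .as_tree(tree)
  rates <- match.arg(rates)
  output <- match.arg(output)
  if (rates == "gamma" && (is.null(alpha) || alpha <= 0))
    stop("rates = \"gamma\" needs a positive alpha", call. = FALSE)
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is required", call. = FALSE)
  if (nsites < 1 || nsim < 1) stop("need nsites >= 1 and nsim >= 1",
                                   call. = FALSE)
  if (symmetrize && output == "alignment")
    stop("symmetrize applies to pattern counts, not alignments", call. = FALSE)

  one_rep <- function(i) {
    set.seed(as.integer(seed + i))
    r <- if (rates == "gamma")
      stats::rgamma(nsites, shape = alpha, rate = alpha) else rep(1, nsites)
    root <- sample.int(4L, nsites, replace = TRUE)
    tips <- matrix(0L, 4L, nsites)
    if (tree$topology == "star") {
      for (k in 1:4) tips[k, ] <- .evolve_branch(root, tree$b[k], r)
    } else {
      left <- .LEFT_TIPS[[tree$topology]]
      right <- setdiff(1:4, left)
      other <- .evolve_branch(root, tree$b5, r)
      for (k in left)  tips[k, ] <- .evolve_branch(root, tree$b[k], r)
      for (k in right) tips[k, ] <- .evolve_branch(other, tree$b[k], r)
    }
    if (output == "alignment") {
      m <- matrix(.NUC[tips], 4L, nsites, dimnames = list(paste0("S", 1:4), NULL))
      return(m)
    }
    cnt <- .new_pattern_counts(tabulate(.PATTERN_LOOKUP[t(tips)], 15L))
    if (symmetrize) cnt <- symmetrize_counts(cnt, trim = TRUE)
    cnt
  }
  stats::setNames(lapply(seq_len(nsim), one_rep),
                  paste0("rep", seq_len(nsim)))
}

#' Simulate pattern counts from a fitted quartet model
#'
#' Parametric simulation from the fitted tree, rate model and alignment
#' length of a [quartet_ml()] fit.
#'
#' @param object A `quartet_ml` fit.
#' @param nsim Number of replicates.
#' @param seed Integer base seed.
#' @param ... Passed to [simulate_quartet()] (e.g. `output`,
#'   `symmetrize`).
#' @return A list of length `nsim` (see [simulate_quartet()]).
#' @export
simulate.quartet_ml <- function(object, nsim = 1, seed = 1, ...) {
  simulate_quartet(object$tree, rates = object$rates, alpha = object$alpha,
                   nsites = sum(object$counts), nsim = nsim, seed = seed,
                   ...)
}

.default_adjust <- function(spec, delta) {
  # change n4 by delta; absorb the 3*delta site change proportionally in
  # the site totals of n1, n2 (6 sites per unit) and n5, keeping the
  # alignment length constant and all counts non-negative integers
  spec <- as.numeric(spec)
  out <- spec
  out[4] <- spec[4] + delta
  if (out[4] < 0) stop("adjusted n4 is negative", call. = FALSE)
  sites <- spec[c(1, 2, 5)] * c(1, 6, 1)
  target <- sum(sites) - 3 * delta
  if (target < 0)
    stop("cannot preserve alignment length with non-negative counts",
         call. = FALSE)
  if (sum(sites) > 0) {
    scale <- target / sum(sites)
    out[1] <- round(spec[1] * scale)
    out[2] <- round(spec[2] * scale)
  }
  out[5] <- target - out[1] - 6 * out[2]
  if (any(out < 0))
    stop("cannot preserve alignment length with non-negative counts",
         call. = FALSE)
  out
}

#' Sweep the star-tree test statistic against the G4 excess
#'
#' Starting from a base `(n1..n5)` specification, changes the number of
#' parsimony-informative pattern units `n4` by each value in `delta` and
#' re-runs the star-vs-resolved likelihood-ratio test, producing the curve
#' of `2dlnL` against `n4 - n3`.  By default `n1`, `n2` and `n5` are
#' rebalanced proportionally so every adjusted spec keeps the base
#' alignment length (`n3` is never touched); supply `adjust` to use a
#' different rule (`function(spec, delta)` returning a length-5 spec).
#'
#' @param base Length-5 base specification.
#' @param delta Integer changes applied to `n4`.
#' @param rates Rate models to run (`"constant"`, `"gamma"` or both).
#' @param adjust Optional replacement for the default length-preserving
#'   adjustment.
#' @inheritParams quartet_ml
#' @return A data frame with one row per `delta` x rate model: the
#'   adjusted spec, `d43 = n4 - n3`, `lnL_star`, `lnL_resolved`,
#'   `statistic` and `p.value`.
#' @examples
#' \donttest{
#' sweep_informative(c(168, 216, 156, 120, 80), delta = c(0, 60, 120))
#' }
#' @export
sweep_informative <- function(base, delta, rates = "constant",
                              b_max = 10, b_min = 0,
                              alpha_max = 1e4, alpha_min = 1e-3,
                              adjust = NULL, control = list()) {
  if (length(base) != 5L) stop("base must be a length-5 spec", call. = FALSE)
  if (is.null(adjust)) adjust <- .default_adjust
  rows <- list()
  for (d in delta) {
    spec <- adjust(base, d)
    if (length(spec) != 5L || any(spec < 0))
      stop("adjustment produced an invalid spec", call. = FALSE)
    for (rt in rates) {
      lrt <- star_test(pattern_counts(spec), rates = rt, b_max = b_max,
                       b_min = b_min, alpha_max = alpha_max,
                       alpha_min = alpha_min, control = control)
      rows[[length(rows) + 1L]] <- data.frame(
        delta = d, n1 = spec[1], n2 = spec[2], n3 = spec[3], n4 = spec[4],
        n5 = spec[5], d43 = spec[4] - spec[3], model = rt,
        lnL_star = lrt$lnL_star, lnL_resolved = lrt$lnL_resolved,
        statistic = lrt$statistic, p.value = lrt$p.value)
    }
  }
  do.call(rbind, rows)
}
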