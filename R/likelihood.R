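# Pruning-algorithm likelihood of the 15 site-pattern classes on star and
# resolved quartet trees.  Likelihood is always computed per class and then
# weighted by counts: the 256 -> 15 collapse is the efficiency contract
# that keeps a continuous-gamma evaluation down to 15 one-dimensional
# integrals.

.TOPOLOGIES <- c("star", "12|34", "13|24", "14|23")
.LEFT_TIPS <- list("12|34" = c(1L, 2L), "13|24" = c(1L, 3L), "14|23" = c(1L, 4L))

#' Construct a quartet tree
#'
#' A quartet is either the star tree (one central node, four terminal
#' branches, the internal branch structurally zero) or one of the three
#' resolved pairings `12|34`, `13|24`, `14|23` with an internal branch
#' `b5 >= 0`.  Branch lengths are in expected substitutions per site and
#' correspond to the terminal branches of OTUs S1..S4 plus the internal
#' branch.
#'
#' @param topology `"star"`, `"12|34"`, `"13|24"` or `"14|23"`.
#' @param b Terminal branch lengths `b1..b4` (a single value is recycled).
#' @param b5 Internal branch length; must be 0 for the star tree.
#' @return An object of class `quartet_tree`.
#' @examples
#' quartet_tree("star", b = 1.2)
#' quartet_tree("12|34", b = c(.8, .8, 1.7, 0), b5 = .85)
#' @export
quartet_tree <- function(topology = .TOPOLOGIES, b, b5 = 0) {
  topology <- match.arg(topology)
  if (length(b) == 1L) b <- rep(b, 4L)
  if (length(b) != 4L || anyNA(b) || any(b < 0) || any(!is.finite(b)))
    stop("b must be 4 finite non-negative terminal branch lengths",
         call. = FALSE)
  if (length(b5) != 1L || is.na(b5) || b5 < 0 || !is.finite(b5))
    stop("b5 must be a single finite non-negative length", call. = FALSE)
  if (topology == "star" && b5 != 0)
    stop("the star tree has no internal branch (b5 must be 0)", call. = FALSE)
  structure(list(topology = topology, b = as.numeric(b), b5 = as.numeric(b5)),
            class = "quartet_tree")
}

#' @export
print.quartet_tree <- function(x, ...) {
  cat("Quartet tree [", x$topology, "]\n", sep = "")
  cat("  b1..b4:", format(x$b, digits = 6), "\n")
  if (x$topology != "star") cat("  b5:    ", format(x$b5, digits = 6), "\n")
  invisible(x)
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Convert a quartet tree to an ape "phylo" object
#'
#' @param x A [quartet_tree()].
#' @param ... Ignored.
#' @return An object of class `phylo` (multifurcating for the star tree).
#' @method as.phylo quartet_tree
#' @export
as.phylo.quartet_tree <- function(x, ...) {
  b <- x$b
  txt <- if (x$topology == "star") {
    sprintf("(S1:%.10f,S2:%.10f,S3:%.10f,S4:%.10f);", b[1], b[2], b[3], b[4])
  } else {
    l <- .LEFT_TIPS[[x$topology]]
    r <- setdiff(1:4, l)
    sprintf("((S%d:%.10f,S%d:%.10f):%.10f,S%d:%.10f,S%d:%.10f);",
            l[1], b[l[1]], l[2], b[l[2]], x$b5, r[1], b[r[1]], r[2], b[r[2]])
  }
  ape::read.tree(text = txt)
}

# Core: likelihood of each class representative column, vectorised over the
# rate multiplier r.  Star: sum over the 4 states of the central node.
# Resolved: double sum over the two internal nodes linked by b5.
# Returns a length(r) x 15 matrix.
.class_lik <- function(b, b5, topology, r) {
  b <- pmax(b, 0); b5 <- max(b5, 0)      # guard finite-difference probes
  nr <- length(r)
  ps <- pd <- matrix(0, nr, 4L)
  for (k in 1:4) {
    e <- exp(-4 * r * b[k] / 3)
    ps[, k] <- 0.25 + 0.75 * e
    pd[, k] <- 0.25 - 0.25 * e
  }
  out <- matrix(0, nr, 15L)
  if (topology == "star") {
    for (cc in 1:15) {
      s <- .PATTERN_REPS[cc, ]
      tot <- 0
      for (x in 1:4) {
        term <- rep.int(0.25, nr)
        for (k in 1:4) term <- term * (if (s[k] == x) ps[, k] else pd[, k])
        tot <- tot + term
      }
      out[, cc] <- tot
    }
  } else {
    left <- .LEFT_TIPS[[topology]]
    right <- setdiff(1:4, left)
    e5 <- exp(-4 * r * b5 / 3)
    ps5 <- 0.25 + 0.75 * e5
    pd5 <- 0.25 - 0.25 * e5
    for (cc in 1:15) {
      s <- .PATTERN_REPS[cc, ]
      tot <- 0
      for (x in 1:4) {
        lterm <- rep.int(0.25, nr)
        for (k in left) lterm <- lterm * (if (s[k] == x) ps[, k] else pd[, k])
        for (y in 1:4) {
          term <- lterm * (if (x == y) ps5 else pd5)
          for (k in right) term <- term * (if (s[k] == y) ps[, k] else pd[, k])
          tot <- tot + term
        }
      }
      out[, cc] <- tot
    }
  }
  out
}

# Composite Gauss-Legendre nodes on (0,1), graded toward both endpoints.
# The gamma integral over rates is mapped to (0,1) by the quantile
# transform r = qgamma(u; alpha, alpha), which absorbs the density exactly
# and keeps the integrand resolved however concentrated (alpha -> 10^4) or
# heavy-tailed (alpha < 1) the rate distribution is.  Validated against
# adaptive quadrature to < 1e-5 lnL units for alpha >= 0.01.
.GAUSS_U <- local({
  brk <- c(0, 5e-4, 5e-3, .05, .2, .5, .8, .95, .99, .999, .9999, .99999, 1)
  xs <- NULL; ws <- NULL
  for (i in seq_len(length(brk) - 1L)) {
    g <- pracma::gaussLegendre(16L, brk[i], brk[i + 1L])
    xs <- c(xs, g$x); ws <- c(ws, g$w)
  }
  list(u = xs, w = ws)
})

# Per-class likelihood integrated over the mean-1 gamma rate distribution.
# Returns a 15-vector.  method "gauss" is the fast fixed rule above;
# "adaptive" calls stats::integrate per class (15 integrals) and serves as
# an accuracy cross-check.
.class_lik_gamma <- function(b, b5, topology, alpha, method = "gauss",
                             rel_tol = 1e-9) {
  if (method == "gauss") {
    r <- stats::qgamma(.GAUSS_U$u, shape = alpha, rate = alpha)
    L <- .class_lik(b, b5, topology, r)
    as.numeric(crossprod(.GAUSS_U$w, L))
  } else {
    vapply(1:15, function(cc) {
      f <- function(u)
        .class_lik(b, b5, topology,
                   stats::qgamma(u, shape = alpha, rate = alpha))[, cc]
      v <- stats::integrate(f, 0, 1, rel.tol = rel_tol, subdivisions = 500L)
      if (v$message != "OK")
        stop("rate integration failed: ", v$message, call. = FALSE)
      v$value
    }, numeric(1L))
  }
}

.safe_log <- function(x) log(pmax(x, 1e-320))

.as_tree <- function(tree) {
  if (!inherits(tree, "quartet_tree"))
    stop("tree must be a quartet_tree object", call. = FALSE)
  tree
}

#' Likelihood of one site-pattern class on a quartet tree
#'
#' Probability of observing the class's representative column, with all
#' branch lengths scaled by the rate multiplier `r`.  Summing
#' `multiplicity * class_likelihood` over the 15 classes gives 1 for any
#' tree and rate.
#'
#' @param class_id Class id 1..15 (vectorised).
#' @param tree A [quartet_tree()].
#' @param r Rate multiplier (single value, >= 0).
#' @return Column probabilities in `(0, 1]`.
#' @export
class_likelihood <- function(class_id, tree, r = 1) {
  tree <- .as_tree(tree)
  if (length(r) != 1L || r < 0) stop("r must be a single non-negative value",
                                     call. = FALSE)
  L <- .class_lik(tree$b, tree$b5, tree$topology, r)
  L[1L, class_id]
}

#' Log-likelihood of pattern counts on a quartet tree
#'
#' Computes `sum_c counts_c * ln L_c` where `L_c` is the per-column
#' likelihood of class `c`, either at rate 1 (`rates = "constant"`) or
#' integrated over the mean-1 gamma rate distribution with shape `alpha`
#' (`rates = "gamma"`; at most 15 one-dimensional integrals).
#'
#' @param x Pattern counts (anything [as_pattern_counts()] accepts: a
#'   length-5 spec, length-15 counts, or a 4-row alignment matrix).
#' @param tree A [quartet_tree()].
#' @param rates `"constant"` or `"gamma"`.
#' @param alpha Gamma shape parameter (required for `rates = "gamma"`).
#' @param quadrature `"gauss"` (fast fixed rule; default) or `"adaptive"`
#'   (`stats::integrate`, used for verification).
#' @return The log-likelihood (a single number, <= 0 for any non-empty
#'   data).
#' @examples
#' tr <- quartet_tree("star", b = 0.426784)
#' quartet_loglik(c(0, 14, 43, 4, 40), tr)            # -1537.68
#' quartet_loglik(c(24, 24, 12, 96, 32),
#'                quartet_tree("star", b = 1.020429),
#'                rates = "gamma", alpha = 10000)     # -2947.797
#' @export
quartet_loglik <- function(x, tree, rates = c("constant", "gamma"),
                           alpha = NULL,
                           quadrature = c("gauss", "adaptive")) {
  counts <- as_pattern_counts(x)
  tree <- .as_tree(tree)
  rates <- match.arg(rates)
  quadrature <- match.arg(quadrature)
  if (rates == "gamma") {
    if (is.null(alpha) || alpha <= 0)
      stop("rates = \"gamma\" needs a positive alpha", call. = FALSE)
    L <- .class_lik_gamma(tree$b, tree$b5, tree$topology, alpha, quadrature)
  } else {
    L <- .class_lik(tree$b, tree$b5, tree$topology, 1)[1L, ]
  }
  active <- as.numeric(counts) > 0
  if (any(L[active] <= 0))
    stop("class likelihood underflowed to zero for an observed class",
         call. = FALSE)
  sum(as.numeric(counts)[active] * log(L[active]))
}

#' Expected site-pattern class probabilities under a tree + rate model
#'
#' The probability that a random alignment column falls in each of the 15
#' classes: multiplicity times the per-column class likelihood
#' (rate-integrated under the gamma model).  Probabilities sum to 1.
#'
#' @inheritParams quartet_loglik
#' @return Named numeric vector of 15 probabilities.
#' @examples
#' p <- site_pattern_probs(quartet_tree("star", b = 100))
#' round(256 * p)   # approaches the multiplicities 24, 24, ..., 4
#' @export
site_pattern_probs <- function(tree, rates = c("constant", "gamma"),
                               alpha = NULL,
                               quadrature = c("gauss", "adaptive")) {
  tree <- .as_tree(tree)
  rates <- match.arg(rates)
  quadrature <- match.arg(quadrature)
  L <- if (rates == "gamma") {
    if (is.null(alpha) || alpha <= 0)
      stop("rates = \"gamma\" needs a positive alpha", call. = FALSE)
    .class_lik_gamma(tree$b, tree$b5, tree$topology, alpha, quadrature)
  } else {
    .class_lik(tree$b, tree$b5, tree$topology, 1)[1L, ]
  }
  p <- .PATTERN_MULT * L
  names(p) <- .CLASS_LABELS
  p
}
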