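# JC69 substitution mathematics.  Equilibrium base frequencies are 1/4 each
# by definition of the model; branch lengths are in expected substitutions
# per site throughout.

#' JC69 transition probability
#'
#' Probability of observing nucleotide `to` at the end of a branch of
#' length `d` that started in state `from`:
#' `1/4 + 3/4 exp(-4d/3)` if the states agree, `1/4 - 1/4 exp(-4d/3)`
#' otherwise.
#'
#' @param from,to Nucleotides (`"A"`, `"C"`, `"G"` or `"T"`).
#' @param d Branch length in expected substitutions per site (>= 0);
#'   vectorised.
#' @return Transition probability (vectorised over `d`).
#' @examples
#' jc69_prob("A", "A", 0)     # 1
#' jc69_prob("A", "C", 1e6)   # 0.25
#' @export
jc69_prob <- function(from, to, d) {
  if (any(d < 0)) stop("branch length must be non-negative", call. = FALSE)
  i <- .site_to_code(from); j <- .site_to_code(to)
  e <- exp(-4 * d / 3)
  ifelse(i == j, 0.25 + 0.75 * e, 0.25 - 0.25 * e)
}

#' JC69 transition probability matrix
#'
#' @param d Branch length (single value, >= 0).
#' @return A 4 x 4 stochastic matrix with rows/columns A, C, G, T.
#' @export
jc69_pmatrix <- function(d) {
  if (length(d) != 1L || d < 0)
    stop("d must be a single non-negative branch length", call. = FALSE)
  e <- exp(-4 * d / 3)
  m <- matrix(0.25 - 0.25 * e, 4L, 4L, dimnames = list(.NUC, .NUC))
  diag(m) <- 0.25 + 0.75 * e
  m
}

#' JC69 distance from a proportion of differing sites
#'
#' Inverts the expected difference proportion `p = 3/4 (1 - exp(-4d/3))`.
#' Used for optimizer starting values and equidistance checks.
#'
#' @param p Proportion of differing sites, `0 <= p < 3/4`.
#' @return Distance in expected substitutions per site.
#' @examples
#' jc69_distance(0)                          # 0
#' jc69_distance(0.75 * (1 - exp(-4 / 3)))   # 1
#' @export
jc69_distance <- function(p) {
  if (any(p < 0) || any(p >= 0.75))
    stop("p must lie in [0, 0.75): the JC69 distance is undefined at ",
         "saturation (p >= 3/4)", call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Mean-one gamma density for site-rate multipliers
#'
#' The rate-heterogeneity model draws a per-site rate multiplier from a
#' gamma distribution with shape `alpha` and rate `alpha`, so the mean rate
#' is 1 and the variance is `1/alpha`.  Large `alpha` approaches the
#' constant-rate model; small `alpha` means strong heterogeneity.
#'
#' @param r Rate multiplier (>= 0); vectorised.
#' @param alpha Shape parameter (> 0).
#' @return Density values.
#' @export
gamma_rate_density <- function(r, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  stats::dgamma(r, shape = alpha, rate = alpha)
}
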