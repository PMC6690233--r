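# Independent oracles and fixture generators.
#
# The column-likelihood oracle deliberately shares nothing with the package
# internals: transition matrices come from the matrix exponential of the
# JC69 rate matrix (Matrix::expm), and the likelihood is a literal sum over
# all internal-node state assignments of the quartet.

oracle_pmatrix <- function(d) {
  stopifnot(requireNamespace("Matrix", quietly = TRUE))
  Q <- matrix(1 / 3, 4, 4)
  diag(Q) <- -1
  as.matrix(Matrix::expm(Q * d))
}

# col: integer codes 1..4 for the four tips
oracle_column_lik <- function(col, topology, b, b5 = 0, r = 1) {
  P <- lapply(b, function(len) oracle_pmatrix(r * len))
  if (topology == "star") {
    tot <- 0
    for (x in 1:4)
      tot <- tot + 0.25 * P[[1]][x, col[1]] * P[[2]][x, col[2]] *
        P[[3]][x, col[3]] * P[[4]][x, col[4]]
    return(tot)
  }
  left <- switch(topology, "12|34" = c(1, 2), "13|24" = c(1, 3),
                 "14|23" = c(1, 4))
  right <- setdiff(1:4, left)
  P5 <- oracle_pmatrix(r * b5)
  tot <- 0
  for (x in 1:4) for (y in 1:4) {
    term <- 0.25 * P5[x, y]
    for (k in left) term <- term * P[[k]][x, col[k]]
    for (k in right) term <- term * P[[k]][y, col[k]]
    tot <- tot + term
  }
  tot
}

rep_codes <- function() {
  t(vapply(strsplit(pattern_classes()$representative, ""),
           function(s) match(s, c("A", "C", "G", "T")), integer(4)))
}

random_spec <- function() {
  s <- sample.int(60, 5, replace = TRUE) - 1L
  if (all(s == 0)) s[5] <- 5L
  s
}

random_quartet_tree <- function(resolved = FALSE) {
  b <- round(runif(4, 0.05, 2.5), 3)
  if (resolved)
    quartet_tree(sample(c("12|34", "13|24", "14|23"), 1), b = b,
                 b5 = round(runif(1, 0, 1.5), 3))
  else
    quartet_tree("star", b = b)
}
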