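# Site-pattern combinatorics for four aligned sequences under JC69.
#
# With four OTUs there are 4^4 = 256 raw site patterns.  JC69 is blind to
# which nucleotides are involved, so patterns collapse into 15 equivalence
# classes determined solely by how the four OTUs are partitioned by shared
# nucleotide.  The classes group further into G1..G5:
#   G1  all four different          1 class,  multiplicity 24
#   G2  three distinct (one pair)   6 classes, multiplicity 24 each (144)
#   G3  3 + 1 split                 4 classes, multiplicity 12 each (48)
#   G4  2 + 2 split (informative)   3 classes, multiplicity 12 each (36)
#   G5  monomorphic                 1 class,  multiplicity 4
# Class ids 1..15 follow this order; within G2 the classes are indexed by
# which OTU pair shares the duplicated nucleotide (12, 13, 14, 23, 24, 34),
# within G3 by which OTU carries the odd nucleotide, within G4 by the
# pairing (12|34, 13|24, 14|23).  This ordering is part of the public
# contract: it fixes the canonical alignment built by quartet_alignment().

.NUC <- c("A", "C", "G", "T")

# canonical representative columns, one per class (integer codes 1..4)
.PATTERN_REPS <- rbind(
  c(1L, 2L, 3L, 4L),                                     # G1
  c(1L, 1L, 2L, 3L), c(1L, 2L, 1L, 3L), c(1L, 2L, 3L, 1L),
  c(2L, 1L, 1L, 3L), c(2L, 1L, 3L, 1L), c(2L, 3L, 1L, 1L),  # G2
  c(2L, 1L, 1L, 1L), c(1L, 2L, 1L, 1L), c(1L, 1L, 2L, 1L), c(1L, 1L, 1L, 2L), # G3
  c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L), c(1L, 2L, 2L, 1L), # G4
  c(1L, 1L, 1L, 1L)                                      # G5
)

.PATTERN_GROUP <- c("G1", rep("G2", 6), rep("G3", 4), rep("G4", 3), "G5")
.PATTERN_MULT <- c(24, rep(24, 6), rep(12, 4), rep(12, 3), 4)
.GROUP_IDX <- list(G1 = 1L, G2 = 2:7, G3 = 8:11, G4 = 12:14, G5 = 15L)
.CLASS_LABELS <- c("G1", paste0("G2:", c("12", "13", "14", "23", "24", "34")),
                   paste0("G3:", 1:4), paste0("G4:", c("12|34", "13|24", "14|23")),
                   "G5")
# weight of one unit of n_i in alignment columns: G2 spans 6 columns etc.
.SPEC_WEIGHT <- c(1, 6, 4, 3, 1)

.classify_code <- function(s) {
  # s: integer vector of 4 nucleotide codes; returns class id 1..15
  same12 <- s[1] == s[2]; same13 <- s[1] == s[3]; same14 <- s[1] == s[4]
  same23 <- s[2] == s[3]; same24 <- s[2] == s[4]; same34 <- s[3] == s[4]
  n_distinct <- length(unique(s))
  if (n_distinct == 4L) return(1L)
  if (n_distinct == 1L) return(15L)
  if (n_distinct == 3L) {  # G2: exactly one sharing pair
    pair <- which(c(same12, same13, same14, same23, same24, same34))
    return(1L + pair)
  }
  # two distinct nucleotides: 3+1 (G3) or 2+2 (G4)
  tab <- tabulate(s, 4L)
  if (max(tab) == 3L) {                       # G3, indexed by the odd OTU
    odd_nuc <- which(tab == 1L)
    return(7L + which(s == odd_nuc))
  }
  # G4, indexed by the partner of OTU 1
  partner <- which(c(same12, same13, same14))
  11L + partner
}

# full 256-entry lookup, built once at install time
.PATTERN_LOOKUP <- local({
  lut <- array(0L, dim = c(4, 4, 4, 4))
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4)
    lut[a, b, cc, d] <- .classify_code(c(a, b, cc, d))
  lut
})

.site_to_code <- function(x) {
  code <- match(toupper(x), .NUC)
  if (anyNA(code))
    stop("invalid nucleotide symbol(s): ",
         paste(unique(x[is.na(code)]), collapse = ", "),
         "; only A, C, G, T are allowed", call. = FALSE)
  code
}

#' The 15 JC69 site-pattern classes for four sequences
#'
#' Enumerates the equivalence classes into which the 256 possible
#' four-sequence site patterns collapse under JC69, in canonical order:
#' the all-different class (G1), the six three-nucleotide classes (G2,
#' indexed by the OTU pair sharing the duplicated base), the four 3+1
#' classes (G3, indexed by the odd OTU), the three 2+2 parsimony-informative
#' classes (G4: 12|34, 13|24, 14|23) and the monomorphic class (G5).
#'
#' @return A data frame with one row per class and columns `class_id`,
#'   `group`, `label`, `representative` (the canonical column, e.g.
#'   `"AACC"`) and `multiplicity` (how many of the 256 raw patterns the
#'   class absorbs; multiplicities sum to 256).
#' @examples
#' pattern_classes()
#' sum(pattern_classes()$multiplicity)  # 256
#' @export
pattern_classes <- function() {
  data.frame(
    class_id = 1:15,
    group = .PATTERN_GROUP,
    label = .CLASS_LABELS,
    representative = apply(.PATTERN_REPS, 1L, function(s) paste(.NUC[s], collapse = "")),
    multiplicity = .PATTERN_MULT,
    stringsAsFactors = FALSE
  )
}

#' Classify a single alignment column
#'
#' @param site The column: a character vector of four nucleotides, or a
#'   single 4-character string (e.g. `"AACC"`).
#' @return A list with elements `class_id` (1..15), `group` (`"G1"` ..
#'   `"G5"`) and `label` (the class label, e.g. `"G4:12|34"`).
#' @examples
#' classify_site(c("A", "C", "G", "T"))$group   # "G1"
#' classify_site("AACC")$label                  # "G4:12|34"
#' @export
classify_site <- function(site) {
  if (is.character(site) && length(site) == 1L && nchar(site) == 4L)
    site <- strsplit(site, "")[[1L]]
  if (length(site) != 4L)
    stop("a site pattern has exactly 4 nucleotides", call. = FALSE)
  id <- .PATTERN_LOOKUP[matrix(.site_to_code(site), 1L)]
  list(class_id = id, group = .PATTERN_GROUP[id], label = .CLASS_LABELS[id])
}

.new_pattern_counts <- function(counts) {
  counts <- as.numeric(counts)
  names(counts) <- .CLASS_LABELS
  structure(counts, class = "pattern_counts")
}

#' Pattern counts from a compact (n1, ..., n5) specification
#'
#' A combination `(n1, n2, n3, n4, n5)` specifies an equidistant quartet
#' alignment: `n1` all-different columns, `n2` copies of *each* of the six
#' G2 classes, `n3` copies of each of the four G3 classes, `n4` copies of
#' each of the three G4 classes and `n5` monomorphic columns, for a total
#' length of `n1 + 6*n2 + 4*n3 + 3*n4 + n5`.  Any such alignment has all
#' six pairwise difference counts equal to `n1 + 5*n2 + 2*n3 + 2*n4`.
#'
#' @param n1,n2,n3,n4,n5 Non-negative integers; alternatively pass a single
#'   length-5 vector as `n1`.
#' @return A `pattern_counts` object: a named numeric vector of the 15
#'   per-class counts.
#' @examples
#' pattern_counts(24, 24, 12, 12, 4)   # every raw pattern exactly once
#' sum(pattern_counts(24, 24, 12, 96, 32))  # 536 sites
#' @seealso [quartet_alignment()], [as_pattern_counts()], [pattern_spec()]
#' @export
pattern_counts <- function(n1, n2, n3, n4, n5) {
  if (missing(n2) && length(n1) == 5L) {
    spec <- as.numeric(n1)
  } else {
    spec <- c(n1, n2, n3, n4, n5)
  }
  if (length(spec) != 5L || anyNA(spec) || any(spec < 0) ||
      any(spec != round(spec)))
    stop("the specification must be 5 non-negative integers", call. = FALSE)
  if (all(spec == 0))
    stop("the specification must contain at least one site", call. = FALSE)
  .new_pattern_counts(spec[c(1, rep(2, 6), rep(3, 4), rep(4, 3), 5)])
}

#' Coerce to per-class site-pattern counts
#'
#' Methods exist for `pattern_counts` (identity), numeric vectors (length 5
#' is read as an `(n1..n5)` specification, length 15 as raw per-class
#' counts), character matrices (4 rows = OTUs, columns = sites) and `DNAbin`
#' alignments as returned by [ape::read.FASTA()].
#'
#' @param x Object to coerce.
#' @param ... Passed on to methods.
#' @return A `pattern_counts` object.
#' @export
as_pattern_counts <- function(x, ...) UseMethod("as_pattern_counts")

#' @export
as_pattern_counts.pattern_counts <- function(x, ...) x

#' @export
as_pattern_counts.numeric <- function(x, ...) {
  if (length(x) == 5L) return(pattern_counts(x))
  if (length(x) == 15L) {
    if (any(x < 0) || anyNA(x))
      stop("per-class counts must be non-negative", call. = FALSE)
    return(.new_pattern_counts(x))
  }
  stop("numeric input must have length 5 (n1..n5 spec) or 15 (class counts)",
       call. = FALSE)
}

#' @export
as_pattern_counts.integer <- function(x, ...) as_pattern_counts(as.numeric(x))

#' @rdname as_pattern_counts
#' @param drop_ambiguous Drop columns containing symbols outside A/C/G/T
#'   (gaps, ambiguity codes) instead of raising an error.  Off by default
#'   because silently dropping sites changes the log-likelihood.
#' @export
as_pattern_counts.matrix <- function(x, drop_ambiguous = FALSE, ...) {
  if (nrow(x) != 4L)
    stop("a quartet alignment must have exactly 4 sequences", call. = FALSE)
  xc <- toupper(x)
  code <- match(xc, .NUC)
  dim(code) <- dim(xc)
  bad <- colSums(is.na(code)) > 0L
  if (any(bad)) {
    if (!drop_ambiguous)
      stop(sum(bad), " column(s) contain non-ACGT symbols; ",
           "use drop_ambiguous = TRUE to discard them", call. = FALSE)
    code <- code[, !bad, drop = FALSE]
  }
  if (ncol(code) == 0L)
    stop("no usable alignment columns", call. = FALSE)
  ids <- .PATTERN_LOOKUP[t(code)]
  .new_pattern_counts(tabulate(ids, 15L))
}

#' @export
as_pattern_counts.DNAbin <- function(x, drop_ambiguous = FALSE, ...) {
  m <- toupper(as.character(as.matrix(x)))
  as_pattern_counts(m, drop_ambiguous = drop_ambiguous)
}

#' @export
print.pattern_counts <- function(x, ...) {
  n <- sum(x)
  cat("Quartet site-pattern counts (", format(n), " sites)\n", sep = "")
  tab <- data.frame(label = .CLASS_LABELS, count = as.numeric(x))
  print(tab, row.names = FALSE)
  spec <- pattern_spec(x)
  if (!anyNA(spec))
    cat("Spec (n1..n5): (", paste(spec, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Recover the (n1..n5) specification from pattern counts
#'
#' @param x A `pattern_counts` object (or anything [as_pattern_counts()]
#'   accepts).
#' @return The length-5 specification, or `NA`s if the counts are not equal
#'   within every group (in which case no spec represents them exactly).
#' @export
pattern_spec <- function(x) {
  x <- as_pattern_counts(x)
  per_group <- lapply(.GROUP_IDX, function(i) unname(x[i]))
  if (any(!vapply(per_group, function(v) all(v == v[1L]), logical(1L))))
    return(rep(NA_real_, 5L))
  vapply(per_group, `[`, numeric(1L), 1L)
}

#' Build the canonical alignment for an (n1..n5) specification
#'
#' Concatenates the canonical representative columns in class order
#' (G1, the six G2 classes, the four G3 classes, the three G4 classes, G5),
#' each class repeated according to its count.  JC69 is blind to the actual
#' nucleotides used, so any quantity computed under JC69 depends only on
#' the specification, not on this choice of representatives.
#'
#' @inheritParams pattern_counts
#' @return A 4 x L character matrix with rownames `S1..S4`.
#' @examples
#' a <- quartet_alignment(24, 24, 12, 96, 32)
#' dim(a)                       # 4 x 536
#' pattern_spec(as_pattern_counts(a))  # round-trips
#' @export
quartet_alignment <- function(n1, n2, n3, n4, n5) {
  counts <- if (missing(n2)) as_pattern_counts(n1) else pattern_counts(n1, n2, n3, n4, n5)
  cols <- lapply(1:15, function(cc) {
    k <- counts[[cc]]
    if (k == 0) NULL else matrix(rep(.NUC[.PATTERN_REPS[cc, ]], k), nrow = 4L)
  })
  out <- do.call(cbind, cols)
  rownames(out) <- paste0("S", 1:4)
  out
}

#' Equalize pattern counts within each group
#'
#' Replaces the per-class counts within each of G2, G3 and G4 by the group
#' total divided equally across the group's classes (G1 and G5 are single
#' classes and untouched).  The result supports the three resolved
#' topologies exactly equally.  By default an indivisible group total is an
#' error, so that dataset construction stays exact; `trim = TRUE` instead
#' drops the remainder sites (shortening the alignment by at most 2 + 3 + 2
#' columns), which is what the simulator uses on stochastic replicates.
#'
#' @param x Pattern counts (anything [as_pattern_counts()] accepts).
#' @param trim Drop remainder sites instead of erroring when a group total
#'   is not divisible by the group size.
#' @return A `pattern_counts` object with equal counts within every group.
#' @examples
#' x <- as_pattern_counts(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3, 6, 9, 0))
#' symmetrize_counts(x)[12:14]   # 6 6 6
#' @export
symmetrize_counts <- function(x, trim = FALSE) {
  x <- as_pattern_counts(x)
  out <- as.numeric(x)
  for (g in c("G2", "G3", "G4")) {
    idx <- .GROUP_IDX[[g]]
    tot <- sum(out[idx])
    size <- length(idx)
    if (tot %% size != 0) {
      if (!trim)
        stop("group ", g, " total (", tot, ") is not divisible by ", size,
             "; use trim = TRUE to drop the remainder", call. = FALSE)
      tot <- tot - tot %% size
    }
    out[idx] <- tot / size
  }
  .new_pattern_counts(out)
}

# per-class pairwise-difference indicators: 15 x 6 (pairs 12,13,14,23,24,34)
.PAIR_IDX <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
.CLASS_PAIR_DIFF <- local({
  m <- matrix(0L, 15L, 6L)
  for (cc in 1:15) for (p in 1:6)
    m[cc, p] <- as.integer(.PATTERN_REPS[cc, .PAIR_IDX[p, 1]] !=
                           .PATTERN_REPS[cc, .PAIR_IDX[p, 2]])
  m
})

#' Pairwise difference counts implied by pattern counts
#'
#' For counts built from an `(n1..n5)` spec all six values are equal
#' (`n1 + 5*n2 + 2*n3 + 2*n4`): the sequences are equidistant.
#'
#' @param x Pattern counts (anything [as_pattern_counts()] accepts).
#' @return Named numeric vector of the 6 pairwise Hamming distances
#'   (in sites), pairs ordered 12, 13, 14, 23, 24, 34.
#' @export
pairwise_differences <- function(x) {
  x <- as_pattern_counts(x)
  out <- as.numeric(t(.CLASS_PAIR_DIFF) %*% as.numeric(x))
  names(out) <- apply(.PAIR_IDX, 1L, paste, collapse = "-")
  out
}

#' Read a four-sequence FASTA alignment
#'
#' @param file Path to a FASTA file with exactly four equal-length
#'   nucleotide sequences.
#' @param drop_ambiguous Drop columns containing non-ACGT symbols instead of
#'   raising an error.
#' @return A 4 x L character matrix (uppercase A/C/G/T).
#' @export
read_quartet_fasta <- function(file, drop_ambiguous = FALSE) {
  x <- ape::read.FASTA(file)
  if (length(x) != 4L)
    stop("expected exactly 4 sequences, found ", length(x), call. = FALSE)
  if (length(unique(lengths(x))) != 1L)
    stop("sequences must be aligned (equal lengths)", call. = FALSE)
  m <- toupper(as.character(as.matrix(x)))
  code <- match(m, .NUC); dim(code) <- dim(m)
  bad <- colSums(is.na(code)) > 0L
  if (any(bad)) {
    if (!drop_ambiguous)
      stop(sum(bad), " column(s) contain non-ACGT symbols; ",
           "use drop_ambiguous = TRUE to discard them", call. = FALSE)
    m <- m[, !bad, drop = FALSE]
  }
  m
}

#' Write a quartet alignment to FASTA
#'
#' @param x A 4 x L character matrix (as from [quartet_alignment()] or
#'   [simulate_quartet()]).
#' @param file Output path.
#' @export
write_quartet_fasta <- function(x, file) {
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  ape::write.FASTA(ape::as.DNAbin(tolower(x)), file)
  invisible(file)
}
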