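# Diversity estimators for haploid sequence: Watterson's theta from the
# count of segregating sites, and nucleotide diversity pi as the mean
# pairwise per-site difference. The denominator L is the surveyed sequence
# length in bp (for this pipeline, the total single-copy Y length), not
# the number of variant columns: constant sites contribute zero
# differences but real sequence.

.subsetMatrix <- function(gm, samples = NULL) {
  m <- if (is(gm, "GenotypeMatrix")) t(assay(gm, "gt")) else gm
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(m))
    if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
    m <- m[samples, , drop = FALSE]
  }
  if (anyNA(m)) stop("matrix has missing cells; impute first")
  m
}

#' Count sites segregating within a sample subset
#' @param gm A [GenotypeMatrix-class] or samples x sites 0/1 matrix.
#' @param samples Optional sample ids defining the subset.
#' @return Integer count of polymorphic columns.
#' @export
segregatingSites <- function(gm, samples = NULL) {
  m <- .subsetMatrix(gm, samples)
  cs <- colSums(m)
  sum(cs > 0L & cs < nrow(m))
}

#' Watterson's theta per site
#'
#' `theta = S / (a_n * L)` with `a_n = sum(1/i, i = 1..n-1)` and S the
#' number of sites segregating within the subset.
#'
#' @inheritParams segregatingSites
#' @param L Denominator sequence length in bp (the surveyed single-copy
#'   length, e.g. 2,390,000 for a 2.39 Mbp scY complement).
#' @return Theta per site.
#' @export
wattersonTheta <- function(gm, L, samples = NULL) {
  m <- .subsetMatrix(gm, samples)
  n <- nrow(m)
  if (n < 2L) stop("need at least two samples")
  stopifnot(L > 0)
  S <- segregatingSites(m)
  an <- sum(1 / seq_len(n - 1L))
  S / (an * L)
}

#' Nucleotide diversity (pi) per site
#'
#' Mean Hamming distance over all n(n-1)/2 unordered sample pairs, divided
#' by `L`. Samples sharing a haplotype contribute zero-distance pairs. The
#' uncorrected pairwise mean is used (no n/(n-1) factor).
#'
#' @inheritParams wattersonTheta
#' @return Pi per site.
#' @export
nucleotideDiversity <- function(gm, L, samples = NULL) {
  m <- .subsetMatrix(gm, samples)
  n <- nrow(m)
  if (n < 2L) stop("need at least two samples")
  stopifnot(L > 0)
  d <- dist(m, method = "manhattan")
  mean(d) / L
}

#' Diversity table over named sample subsets
#'
#' @inheritParams wattersonTheta
#' @param subsets Named list of sample-id vectors.
#' @return data.frame: subset, n, S, L, theta, pi.
#' @export
diversityTable <- function(gm, L, subsets) {
  rows <- lapply(names(subsets), function(nm) {
    ss <- subsets[[nm]]
    data.frame(subset = nm, n = length(ss),
               S = segregatingSites(gm, ss), L = L,
               theta = wattersonTheta(gm, L, ss),
               pi = nucleotideDiversity(gm, L, ss),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
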