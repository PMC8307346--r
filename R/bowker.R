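# Bowker's matched-pairs symmetry test on the 4x4 site-pattern count matrix
# of two aligned sequences, and the pairwise p-value matrix over an
# alignment. Rejection indicates violation of stationarity / reversibility /
# homogeneity between the two sequences.

#' 4x4 divergence count matrix of two aligned sequences
#'
#' `n[i, j]` is the number of sites carrying base i in the first sequence
#' and base j in the second, over sites that are unambiguous A/C/G/T in
#' both (gaps and ambiguities excluded).
#'
#' @param seqA,seqB equal-length (gapped) nucleotide strings or vectors.
#' @return 4x4 integer matrix with dimnames A, C, G, T.
#' @export
divergence_matrix_counts <- function(seqA, seqB) {
  a <- if (length(seqA) == 1L) .s2v(toupper(seqA)) else toupper(seqA)
  b <- if (length(seqB) == 1L) .s2v(toupper(seqB)) else toupper(seqB)
  if (length(a) != length(b)) stop("sequences differ in length")
  use <- .is_acgt(a) & .is_acgt(b)
  lv <- c("A", "C", "G", "T")
  as.matrix(table(factor(a[use], lv), factor(b[use], lv)))
}

#' Bowker's matched-pairs symmetry test
#'
#' chi2 = sum over unordered base pairs (i, j), i < j, with n_ij + n_ji > 0
#' of (n_ij - n_ji)^2 / (n_ij + n_ji); the degrees of freedom count only
#' those realizable pairs (the SymTest convention — zero-count pairs are
#' common in short genes). df = 0 yields chi2 = 0, p = 1.
#'
#' @param n 4x4 count matrix from [divergence_matrix_counts()].
#' @return list of class `symmetry_test` with `chi2`, `df`, `p`.
#' @export
bowker <- function(n) {
  stopifnot(is.matrix(n), all(dim(n) == c(4L, 4L)), all(n >= 0))
  chi2 <- 0
  df <- 0L
  for (i in 1:3) {
    for (j in (i + 1L):4L) {
      den <- n[i, j] + n[j, i]
      if (den > 0) {
        chi2 <- chi2 + (n[i, j] - n[j, i])^2 / den
        df <- df + 1L
      }
    }
  }
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p), class = "symmetry_test")
}

#' @export
print.symmetry_test <- function(x, ...) {
  cat(sprintf("Bowker symmetry test: chi2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Pairwise Bowker symmetry p-value matrix
#'
#' Bowker's test for every unordered taxon pair of an alignment. The
#' diagonal is 1 and the matrix is symmetric (the statistic does not depend
#' on sequence order). Pairs with p > `alpha` are the ones that do not
#' violate the stationarity/reversibility/homogeneity assumptions.
#'
#' @param aln a [mito_alignment()].
#' @param alpha threshold used for the `pass` indicator matrix.
#' @return list with `taxa`, `p` (symmetric matrix), `chi2`, and logical
#'   `pass` (`p > alpha`).
#' @export
pairwise_symmetry <- function(aln, alpha = 0.05) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  p <- matrix(1, n, n, dimnames = list(aln$taxa, aln$taxa))
  chi2 <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      bt <- bowker(divergence_matrix_counts(m[i, ], m[j, ]))
      p[i, j] <- p[j, i] <- bt$p
      chi2[i, j] <- chi2[j, i] <- bt$chi2
    }
  }
  list(taxa = aln$taxa, p = p, chi2 = chi2, pass = p > alpha)
}

#' Long-format export of a pairwise symmetry matrix
#'
#' @param sym output of [pairwise_symmetry()].
#' @return data frame with one row per unordered pair: `taxonA`, `taxonB`,
#'   `chi2`, `p`, `pass`.
#' @export
symmetry_table <- function(sym) {
  n <- length(sym$taxa)
  idx <- which(upper.tri(sym$p), arr.ind = TRUE)
  data.frame(taxonA = sym$taxa[idx[, 1L]], taxonB = sym$taxa[idx[, 2L]],
             chi2 = sym$chi2[idx], p = sym$p[idx], pass = sym$pass[idx],
             stringsAsFactors = FALSE)
}
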