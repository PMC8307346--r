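# Kimura 2-parameter pairwise distances with pairwise deletion of gapped or
# ambiguous sites. Transitions are A<->G and C<->T; everything else is a
# transversion.

#' @keywords internal
.purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites with a gap or ambiguity in either sequence are excluded (pairwise
#' deletion). With P the transition fraction and Q the transversion fraction
#' over usable sites, d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q). When either
#' logarithm argument is non-positive the distance is saturated and the
#' undefined-distance sentinel `NA` is returned (with attribute
#' `saturated = TRUE`).
#'
#' @param seqA,seqB equal-length (gapped) nucleotide strings or character
#'   vectors.
#' @return the distance, or `NA` if saturated; attributes `P`, `Q`,
#'   `n_sites` carry the ingredients.
#' @export
k2p <- function(seqA, seqB) {
  a <- if (length(seqA) == 1L) .s2v(toupper(seqA)) else toupper(seqA)
  b <- if (length(seqB) == 1L) .s2v(toupper(seqB)) else toupper(seqB)
  if (length(a) != length(b)) stop("sequences differ in length")
  use <- .is_acgt(a) & .is_acgt(b)
  n <- sum(use)
  if (n < 1L) stop("no usable sites")
  a <- a[use]; b <- b[use]
  diff <- a != b
  ts <- diff & (.purine[a] == .purine[b])
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  structure(d, P = P, Q = Q, n_sites = n,
            saturated = is.na(d))
}

#' Mean pairwise K2P distance over an alignment
#'
#' Arithmetic mean of the defined pairwise distances over all unordered
#' taxon pairs; saturated (undefined) pairs are excluded and counted.
#'
#' @param aln a [mito_alignment()].
#' @return mean distance with attributes `n_pairs` (defined) and
#'   `n_undefined`. All pairs undefined is an error.
#' @export
gene_mean_k2p <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  d <- c()
  undef <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- suppressWarnings(k2p(m[i, ], m[j, ]))
      if (is.na(dij)) undef <- undef + 1L else d <- c(d, as.numeric(dij))
    }
  }
  if (length(d) == 0L) stop("all pairwise distances undefined (saturation)")
  structure(mean(d), n_pairs = length(d), n_undefined = undef)
}
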