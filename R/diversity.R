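# Nucleotide diversity (Pi) and sliding-window profiles, DnaSP-style:
# Pi is the mean over all unordered taxon pairs of (pairwise differences /
# pairwise usable sites) with pairwise deletion of gaps and ambiguities.

# Pi on a character matrix (taxa x sites); NA if no usable pair.
#' @keywords internal
.pi_matrix <- function(m) {
  n <- nrow(m)
  ok <- matrix(.is_acgt(m), nrow = n)
  tot <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      ns <- sum(use)
      if (ns == 0L) next
      tot <- tot + sum(m[i, use] != m[j, use]) / ns
      np <- np + 1L
    }
  }
  if (np == 0L) NA_real_ else tot / np
}

#' Nucleotide diversity (Pi) of an alignment
#'
#' Mean over all unordered taxon pairs of (pairwise differences / pairwise
#' usable sites), with pairwise deletion of gaps and ambiguities.
#'
#' @param aln a [mito_alignment()].
#' @return Pi in \[0, 1\]; `NA` (with a warning) if no taxon pair has any
#'   usable site.
#' @export
nucleotide_diversity <- function(aln) {
  pi <- .pi_matrix(.aln_matrix(aln))
  if (is.na(pi)) warning("no usable taxon pairs; Pi undefined")
  pi
}

#' Sliding-window nucleotide diversity profile
#'
#' Windows start at alignment position 0 and advance by `step`; only full
#' windows are used, so the last window is the final one that fits entirely
#' within the alignment. Pi per window is [nucleotide_diversity()] on the
#' column slice; the reported midpoint is start + window/2. An alignment
#' shorter than `window` yields a single whole-alignment window with a
#' warning.
#'
#' @param aln a [mito_alignment()].
#' @param window window width, bp (alignment columns).
#' @param step step size, bp.
#' @return data frame with columns `start` (0-based), `midpoint`, `pi`.
#' @export
sliding_window_pi <- function(aln, window = 200L, step = 20L) {
  len <- aln_width(aln)
  m <- .aln_matrix(aln)
  if (len < window) {
    warning("alignment shorter than window; using one whole-alignment window")
    return(data.frame(start = 0L, midpoint = len / 2, pi = .pi_matrix(m)))
  }
  starts <- seq(0L, len - window, by = step)
  pi <- vapply(starts, function(s) {
    .pi_matrix(m[, (s + 1L):(s + window), drop = FALSE])
  }, numeric(1))
  data.frame(start = as.integer(starts),
             midpoint = starts + window / 2, pi = pi)
}
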