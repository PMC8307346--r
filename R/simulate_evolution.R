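# Sequence-evolution simulators with known ground truth: a star-tree K2P
# mutator (every taxon independently derived from the root, so the expected
# pairwise distance is twice the branch length) and a codon-level
# mutation-acceptance evolver with a planted dN/dS ratio.

#' Random coding sequence without stop codons
#'
#' Codons drawn from the 62 sense codons of the invertebrate mitochondrial
#' code, either uniformly or with base-composition-weighted probabilities.
#' Uses the current RNG state.
#'
#' @param n_codons number of codons.
#' @param composition optional named A/C/G/T fractions to bias codon choice.
#' @return nucleotide string of length `3 * n_codons`.
#' @export
random_coding_sequence <- function(n_codons, composition = NULL) {
  gc5 <- genetic_code_5()
  sense <- names(gc5)[gc5 != "*"]
  p <- if (is.null(composition)) NULL else {
    w <- .codon_probs(composition)
    w[sense]
  }
  .v2s(sample(sense, n_codons, replace = TRUE, prob = p))
}

# K2P substitution probabilities at branch length d with ts/tv ratio kappa
# (kappa = alpha/beta). Returns c(p_same, p_ts, p_tv_each).
#' @keywords internal
.k2p_probs <- function(d, kappa) {
  stopifnot(d >= 0, kappa > 0)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)          # each of the two transversions
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

#' Evolve an alignment under the K2P model on a star tree
#'
#' Each taxon is mutated independently from the root with branch length `d`
#' substitutions/site and transition/transversion rate ratio `kappa`
#' (kappa -> Inf gives transitions only). The expected pairwise K2P distance
#' between any two taxa is `2 * d`.
#'
#' @param root root nucleotide string (A/C/G/T).
#' @param n_taxa number of taxa.
#' @param d branch length, expected substitutions per site.
#' @param kappa transition/transversion rate ratio alpha/beta.
#' @param seed RNG seed.
#' @param gene label for the returned alignment.
#' @return a [mito_alignment()] with taxa `t01`, `t02`, ...
#' @export
evolve_k2p <- function(root, n_taxa, d, kappa = 2, seed = 1L, gene = "sim") {
  set.seed(seed)
  rv <- .s2v(toupper(root))
  stopifnot(all(.is_acgt(rv)), n_taxa >= 2L)
  idx <- match(rv, .BASES)                    # 1=A 2=C 3=G 4=T
  ts_partner <- c(3L, 4L, 1L, 2L)             # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)                    # an arbitrary fixed labelling
  tv2 <- c(4L, 3L, 4L, 3L)                    # of the two transversions
  if (is.finite(kappa)) {
    pr <- .k2p_probs(d, kappa)
  } else {
    e <- exp(-2 * d)
    pr <- c(same = 0.5 + 0.5 * e, ts = 0.5 - 0.5 * e, tv = 0)
  }
  L <- length(idx)
  rows <- vapply(seq_len(n_taxa), function(k) {
    u <- stats::runif(L)
    out <- idx
    sel_ts <- u < pr["ts"]
    sel_tv1 <- !sel_ts & u < pr["ts"] + pr["tv"]
    sel_tv2 <- !sel_ts & !sel_tv1 & u < pr["ts"] + 2 * pr["tv"]
    out[sel_ts] <- ts_partner[idx[sel_ts]]
    out[sel_tv1] <- tv1[idx[sel_tv1]]
    out[sel_tv2] <- tv2[idx[sel_tv2]]
    .v2s(.BASES[out])
  }, character(1))
  mito_alignment(gene, stats::setNames(rows, sprintf("t%02d", seq_len(n_taxa))))
}

#' Evolve a codon alignment with a planted dN/dS ratio
#'
#' Mutation-acceptance scheme on a star tree: single-base changes are
#' proposed uniformly over positions and alternative bases; changes creating
#' a stop codon are rejected, synonymous changes are always accepted and
#' non-synonymous changes are accepted with probability `omega`. Because
#' proposals are unbiased over the mutational neighborhood, the realized
#' Nd/Sd ratio converges to the omega-scaled NG86 site ratio and
#' [gene_mean_kaks()] recovers `omega` at moderate divergence.
#'
#' @param root in-frame coding string without stop codons.
#' @param n_taxa number of taxa.
#' @param omega planted dN/dS (>= 0).
#' @param prop_rate expected proposals per nucleotide site per branch;
#'   controls divergence.
#' @param seed RNG seed.
#' @param gene label for the returned alignment.
#' @return a [mito_alignment()].
#' @export
evolve_codons <- function(root, n_taxa, omega, prop_rate = 0.15,
                          seed = 1L, gene = "sim") {
  set.seed(seed)
  stopifnot(omega >= 0, nchar(root) %% 3L == 0L)
  gc5 <- genetic_code_5()
  rv <- .s2v(toupper(root))
  L <- length(rv)
  root_codons <- codon_split(root)$codons
  if (any(gc5[root_codons] == "*")) stop("root contains stop codons")
  rows <- vapply(seq_len(n_taxa), function(k) {
    x <- rv
    n_prop <- stats::rpois(1L, prop_rate * L)
    for (m in seq_len(n_prop)) {
      pos <- sample.int(L, 1L)
      b <- sample(setdiff(.BASES, x[pos]), 1L)
      ci <- (pos - 1L) %/% 3L
      old_codon <- .v2s(x[(3L * ci + 1L):(3L * ci + 3L)])
      new <- x
      new[pos] <- b
      new_codon <- .v2s(new[(3L * ci + 1L):(3L * ci + 3L)])
      aa_old <- gc5[[old_codon]]
      aa_new <- gc5[[new_codon]]
      if (aa_new == "*") next
      if (aa_old == aa_new || stats::runif(1L) < omega) x <- new
    }
    .v2s(x)
  }, character(1))
  mito_alignment(gene, stats::setNames(rows, sprintf("t%02d", seq_len(n_taxa))))
}
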