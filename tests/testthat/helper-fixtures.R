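# Shared fixtures built in code.

# Small annotated genome for unit tests that do not need the full 37-gene
# layout: two PCGs (one on each strand), a tRNA and a control region.
toy_genome <- function() {
  # cox1 (J): ATG AAA TTC TAA           at [0, 12)
  # trnW:     GGGGGG                    at [12, 18)
  # nad1 (N): revcomp(ATT CCT TAA) = TTAAGGAAT at [18, 27)
  # CR:       ACGACGACGACG              at [27, 39)
  seq <- paste0("ATGAAATTCTAA", "GGGGGG", "TTAAGGAAT", "ACGACGACGACG")
  feats <- data.frame(
    name = c("cox1", "trnW", "nad1", "CR"),
    kind = c("PCG", "tRNA", "PCG", "control_region"),
    start = c(0L, 12L, 18L, 27L),
    end = c(12L, 18L, 27L, 39L),
    strand = c("J", "J", "N", "J"),
    codon_start = c(0L, NA, 0L, NA),
    stringsAsFactors = FALSE)
  mito_genome("TOY1", seq, circular = TRUE, features = feats)
}

# full synthetic genome, cached per session (deterministic, seed 42)
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(synthetic_genome_spec(seed = 42L))
    cache
  }
})

# star-tree pair simulated under an explicitly asymmetric process: a
# one-directional A->G pressure on top of light symmetric noise
asymmetric_pair <- function(n_sites, seed, push = 0.10, noise = 0.03) {
  set.seed(seed)
  x <- sample(c("A", "C", "G", "T"), n_sites, TRUE)
  y <- x
  sel <- stats::runif(n_sites) < push & x == "A"
  y[sel] <- "G"
  sel2 <- stats::runif(n_sites) < noise
  y[sel2] <- sample(c("A", "C", "G", "T"), sum(sel2), TRUE)
  list(a = paste0(x, collapse = ""), b = paste0(y, collapse = ""))
}

# Codon alignment with symmetric evolution at positions 1+2 but
# taxon-specific compositional drift at third positions: taxa drift toward
# different third-position base pools, the classic source of among-lineage
# heterogeneity.
third_position_drift_aln <- function(n_taxa, n_codons, seed,
                                     rate12 = 0.02, rate3 = 0.35) {
  set.seed(seed)
  L <- 3L * n_codons
  root <- sample(c("A", "C", "G", "T"), L, TRUE)
  targets <- list(c(.7, .1, .1, .1), c(.1, .7, .1, .1),
                  c(.1, .1, .7, .1), c(.1, .1, .1, .7))
  rows <- vapply(seq_len(n_taxa), function(k) {
    x <- root
    third <- seq(3L, L, by = 3L)
    first2 <- setdiff(seq_len(L), third)
    s12 <- first2[stats::runif(length(first2)) < rate12]
    x[s12] <- sample(c("A", "C", "G", "T"), length(s12), TRUE)
    s3 <- third[stats::runif(length(third)) < rate3]
    x[s3] <- sample(c("A", "C", "G", "T"), length(s3), TRUE,
                    prob = targets[[(k - 1L) %% 4L + 1L]])
    paste0(x, collapse = "")
  }, character(1))
  mito_alignment("drift", stats::setNames(rows, sprintf("t%02d", 1:n_taxa)))
}

random_dna <- function(n, comp = c(A = .425, C = .139, G = .094, T = .342)) {
  paste0(sample(names(comp), n, TRUE, prob = comp), collapse = "")
}
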