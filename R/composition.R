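# Base counting, percentage composition and AT/GC strand skew for the full
# genome and the canonical partitions (PCGs, codon positions, tRNAs, rRNAs,
# control region). Ambiguity codes are tallied separately and excluded from
# every percentage and skew denominator.

#' Count bases in a sequence
#'
#' Case-insensitive A/C/G/T counts; all other symbols (IUPAC ambiguity
#' codes, gaps, N) are tallied in `n_other` and excluded from downstream
#' denominators.
#'
#' @param seq nucleotide string.
#' @return object of class `base_counts`: list with `nA`, `nC`, `nG`, `nT`,
#'   `n_other`.
#' @export
count_bases <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) {
    cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    other <- 0L
  } else {
    af <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
    cnt <- af[c("A", "C", "G", "T")]
    other <- sum(af) - sum(cnt)
  }
  structure(list(nA = unname(cnt["A"]), nC = unname(cnt["C"]),
                 nG = unname(cnt["G"]), nT = unname(cnt["T"]),
                 n_other = as.integer(other)),
            class = "base_counts")
}

#' AT skew, (A - T) / (A + T)
#'
#' Strand compositional asymmetry. Accepts either a [count_bases()] result
#' or two numbers (counts or percentages — the statistic is scale-free).
#' A zero denominator yields the undefined-value sentinel `NA`, not an error.
#'
#' @param x a `base_counts` object, or the A count/percentage.
#' @param t the T count/percentage when `x` is numeric.
#' @return dimensionless skew in \[-1, 1\], or `NA` if A + T = 0.
#' @export
at_skew <- function(x, t = NULL) {
  if (inherits(x, "base_counts")) { a <- x$nA; t <- x$nT } else a <- x
  den <- a + t
  if (is.na(den) || den <= 0) return(NA_real_)
  (a - t) / den
}

#' GC skew, (G - C) / (G + C)
#'
#' @param x a `base_counts` object, or the G count/percentage.
#' @param c_ the C count/percentage when `x` is numeric.
#' @return dimensionless skew in \[-1, 1\], or `NA` if G + C = 0.
#' @export
gc_skew <- function(x, c_ = NULL) {
  if (inherits(x, "base_counts")) { g <- x$nG; c_ <- x$nC } else g <- x
  den <- g + c_
  if (is.na(den) || den <= 0) return(NA_real_)
  (g - c_) / den
}

# one summary row from a sequence
#' @keywords internal
.composition_row <- function(region, seq) {
  bc <- count_bases(seq)
  tot <- bc$nA + bc$nC + bc$nG + bc$nT
  pct <- function(n) if (tot > 0) 100 * n / tot else NA_real_
  data.frame(
    region = region, size_bp = nchar(seq),
    pctA = pct(bc$nA), pctC = pct(bc$nC), pctG = pct(bc$nG), pctT = pct(bc$nT),
    pctAT = pct(bc$nA + bc$nT), pctGC = pct(bc$nG + bc$nC),
    at_skew = at_skew(bc), gc_skew = gc_skew(bc),
    stringsAsFactors = FALSE
  )
}

#' Composition and skew table for the canonical genome partitions
#'
#' One row per region: full genome; concatenated PCGs in coding sense with
#' terminal stop codons (complete or truncated) excluded; 1st/2nd/3rd codon
#' positions of that concatenation; concatenated tRNAs; concatenated rRNAs;
#' control region. Overlapping features are counted once per containing
#' feature (per-gene concatenation, no deduplication). Percentages use the
#' A+C+G+T total as denominator. A missing partition is omitted with a
#' warning.
#'
#' @param genome a [mito_genome()].
#' @return data frame with columns `region`, `size_bp`, `pctA`, `pctC`,
#'   `pctG`, `pctT`, `pctAT`, `pctGC`, `at_skew`, `gc_skew`.
#' @export
region_composition <- function(genome) {
  ft <- genome$features
  rows <- list(.composition_row("Full genome", genome$sequence))

  if (any(ft$kind == "PCG")) {
    codons <- .pcg_codons(genome)                 # stops excluded
    all_codons <- unlist(codons, use.names = FALSE)
    pcg_seq <- .v2s(all_codons)
    rows <- c(rows, list(.composition_row("PCGs", pcg_seq)))
    if (length(all_codons)) {
      cm <- do.call(rbind, strsplit(all_codons, "", fixed = TRUE))
      lab <- c("1st codon position", "2nd codon position",
               "3rd codon position")
      for (p in 1:3) {
        rows <- c(rows, list(.composition_row(lab[p], .v2s(cm[, p]))))
      }
    }
  } else {
    warning("no PCG features; PCG and codon-position rows omitted")
  }

  concat_kind <- function(kind) {
    idx <- which(ft$kind == kind)
    paste0(vapply(idx, function(i) extract_gene_sequence(genome, i),
                  character(1)), collapse = "")
  }
  for (spec in list(c("tRNA", "tRNAs"), c("rRNA", "rRNAs"),
                    c("control_region", "CR"))) {
    if (any(ft$kind == spec[1L])) {
      rows <- c(rows, list(.composition_row(spec[2L], concat_kind(spec[1L]))))
    } else {
      warning("no ", spec[1L], " features; ", spec[2L], " row omitted")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round a composition table for reporting
#'
#' Percentages to 1 decimal and skews to 2, the conventional display
#' precision for mitogenome composition tables.
#'
#' @param comp output of [region_composition()].
#' @return data frame with rounded columns.
#' @export
format_composition <- function(comp) {
  pc <- c("pctA", "pctC", "pctG", "pctT", "pctAT", "pctGC")
  comp[pc] <- lapply(comp[pc], round, digits = 1)
  comp[c("at_skew", "gc_skew")] <-
    lapply(comp[c("at_skew", "gc_skew")], round, digits = 2)
  comp
}
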