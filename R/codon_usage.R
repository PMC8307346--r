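# Codon counting, RSCU and start/stop tabulation under the invertebrate
# mitochondrial genetic code (NCBI translation table 5: AGA/AGG = Ser,
# AUA = Met, UGA = Trp; stops are UAA/UAG only).

# genetic code environment, built once per session
.code_env <- new.env(parent = emptyenv())

#' Invertebrate mitochondrial genetic code (table 5)
#'
#' @return named character vector mapping the 64 DNA codons to one-letter
#'   amino acids, stops as `"*"`.
#' @export
genetic_code_5 <- function() {
  if (is.null(.code_env$gc5)) .code_env$gc5 <- Biostrings::getGeneticCode("5")
  .code_env$gc5
}

#' @keywords internal
.stop_codons <- function() names(which(genetic_code_5() == "*"))

#' Translate DNA codons under code 5
#' @param codons character vector of DNA triplets.
#' @return one-letter amino acids (`"*"` for stops, `NA` for codons with
#'   non-ACGT symbols).
#' @export
translate_codons <- function(codons) {
  unname(genetic_code_5()[codons])
}

#' Pool codon counts over all protein-coding genes
#'
#' Counts codons over the 13 PCGs in coding sense (genome order), excluding
#' stop codons, truncated stop remnants and any codon containing a non-ACGT
#' symbol. Reported in the RNA alphabet (T -> U), with all 64 codons as keys.
#'
#' @param genome a [mito_genome()] with annotated PCGs.
#' @return data frame with columns `codon` (RNA), `aa`, `count`.
#' @export
count_codons <- function(genome) {
  if (!any(genome$features$kind == "PCG")) stop("genome has no annotated PCGs")
  codons <- unlist(.pcg_codons(genome), use.names = FALSE)
  gc5 <- genetic_code_5()
  keep <- codons %in% names(gc5) & !(codons %in% .stop_codons())
  tab <- table(factor(codons[keep], levels = names(gc5)))
  data.frame(codon = chartr("T", "U", names(gc5)),
             aa = unname(gc5),
             count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = X_c / ((1/k) * sum of X over the k synonymous codons of c's
#' amino acid), under the invertebrate mitochondrial code. Stop codons are
#' excluded from the families. A family with total count zero gets RSCU 0
#' for all members and is flagged in `family_unused`.
#'
#' @param counts output of [count_codons()] (or any data frame with `codon`
#'   in the RNA alphabet and `count`).
#' @return data frame with columns `codon`, `aa`, `count`, `family_size`,
#'   `rscu`, `family_unused`.
#' @export
rscu <- function(counts) {
  gc5 <- genetic_code_5()
  dna <- chartr("U", "T", counts$codon)
  aa <- unname(gc5[dna])
  keep <- aa != "*"
  out <- data.frame(codon = counts$codon[keep], aa = aa[keep],
                    count = counts$count[keep], stringsAsFactors = FALSE)
  fam_tot <- tapply(out$count, out$aa, sum)
  fam_size <- tapply(out$count, out$aa, length)
  out$family_size <- as.integer(fam_size[out$aa])
  tot <- as.numeric(fam_tot[out$aa])
  out$rscu <- ifelse(tot > 0, out$count * out$family_size / tot, 0)
  out$family_unused <- tot == 0
  out[order(out$aa, out$codon), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Start and stop codons of every protein-coding gene
#'
#' One row per PCG in genome order. Truncated termination codons (`T`,
#' `TA`, completed by post-transcriptional polyadenylation) are labelled
#' `"T(truncated)"` / `"TA(truncated)"`; non-ATN starts are flagged.
#'
#' @param genome a [mito_genome()] with annotated PCGs.
#' @return data frame with columns `gene`, `start_codon`, `start_is_ATN`,
#'   `stop_codon`, `stop_truncated`.
#' @export
start_stop_table <- function(genome) {
  codons <- .pcg_codons(genome, keep_stop = TRUE)
  rows <- lapply(names(codons), function(g) {
    cv <- codons[[g]]
    rem <- attr(cv, "remnant")
    start <- if (length(cv)) cv[1L] else NA_character_
    if (nzchar(rem)) {
      stop_codon <- paste0(rem, "(truncated)")
      truncated <- TRUE
    } else if (length(cv) && cv[length(cv)] %in% .stop_codons()) {
      stop_codon <- cv[length(cv)]
      truncated <- FALSE
    } else {
      stop_codon <- "none"
      truncated <- FALSE
    }
    data.frame(gene = g, start_codon = start,
               start_is_ATN = grepl("^AT[ACGT]$", start),
               stop_codon = stop_codon, stop_truncated = truncated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
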