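# Small internal helpers shared across modules.

#' @keywords internal
.s2v <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' @keywords internal
.v2s <- function(v) paste0(v, collapse = "")

# Reverse complement of a plain character string (IUPAC and '-' allowed).
#' @keywords internal
.revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' @keywords internal
.is_acgt <- function(v) v %in% c("A", "C", "G", "T")

# Deterministic largest-remainder allocation of n items to probabilities p.
# Guarantees sum(counts) == n and |counts - n*p| < 1 elementwise.
#' @keywords internal
.allocate_counts <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0))
  p <- p / sum(p)
  raw <- n * p
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- raw - counts
    take <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Write a data frame as a tab-separated table
#'
#' Plain TSV writer used for every table the package emits: tab-separated,
#' header row, no quoting, no row names.
#'
#' @param rows data frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
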