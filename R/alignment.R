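# Aligned-FASTA container and I/O. Rows are equal-length gapped sequences
# over {A,C,G,T,-,N,...}; taxa labels come from the FASTA headers.

#' Construct an alignment object
#'
#' @param gene gene label.
#' @param rows named character vector of equal-length gapped sequences; the
#'   names are the taxon labels (unique, at least 2).
#' @return object of class `mito_alignment`.
#' @export
mito_alignment <- function(gene, rows) {
  taxa <- names(rows)
  if (is.null(taxa) || anyNA(taxa) || any(!nzchar(taxa))) {
    stop("rows must be named by taxon")
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (length(rows) < 2L) stop("an alignment needs at least 2 taxa")
  w <- nchar(rows)
  if (length(unique(w)) != 1L) {
    bad <- taxa[w != stats::median(w)]
    stop("ragged alignment; offending taxa: ", paste(bad, collapse = ", "))
  }
  rows <- toupper(rows)
  structure(list(gene = gene, taxa = taxa, rows = unname(rows)),
            class = "mito_alignment")
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat(sprintf("<mito_alignment> %s: %d taxa x %d sites\n",
              x$gene, length(x$taxa), nchar(x$rows[1L])))
  invisible(x)
}

#' Number of alignment columns
#' @param aln a [mito_alignment()].
#' @export
aln_width <- function(aln) nchar(aln$rows[1L])

# character matrix (taxa x sites) view of an alignment
#' @keywords internal
.aln_matrix <- function(aln) {
  m <- do.call(rbind, lapply(aln$rows, .s2v))
  rownames(m) <- aln$taxa
  m
}

#' Read an aligned FASTA file
#'
#' @param path FASTA path.
#' @param gene gene label; defaults to the file name without extension.
#' @return a [mito_alignment()]. Ragged rows or duplicate headers are
#'   errors naming the offending taxon.
#' @export
read_alignment <- function(path, gene = NULL) {
  if (is.null(gene)) gene <- sub("\\.[A-Za-z]+$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(as.character(set), names(set))
  mito_alignment(gene, rows)
}

#' Write an alignment as FASTA
#'
#' @param aln a [mito_alignment()].
#' @param path output path.
#' @return `path`, invisibly. Write/read round-trips preserve the rows
#'   byte-exactly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(stats::setNames(aln$rows, aln$taxa))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Subset alignment columns
#'
#' @param aln a [mito_alignment()].
#' @param cols integer vector of 1-based column indices to keep.
#' @return a [mito_alignment()] restricted to `cols`.
#' @export
aln_subset <- function(aln, cols) {
  m <- .aln_matrix(aln)[, cols, drop = FALSE]
  rows <- stats::setNames(apply(m, 1L, .v2s), aln$taxa)
  mito_alignment(aln$gene, rows)
}

#' Concatenate alignments over the same taxa
#'
#' @param alns list of [mito_alignment()] objects sharing the same taxon set.
#' @param gene label for the concatenation.
#' @return a [mito_alignment()].
#' @export
aln_concat <- function(alns, gene = "concat") {
  taxa <- alns[[1L]]$taxa
  for (a in alns) {
    if (!setequal(a$taxa, taxa)) stop("taxon sets differ across alignments")
  }
  rows <- vapply(taxa, function(tx) {
    paste0(vapply(alns, function(a) a$rows[match(tx, a$taxa)],
                  character(1)), collapse = "")
  }, character(1))
  mito_alignment(gene, rows)
}
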