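# MitoGenome container, gene-name normalization, sequence extraction and
# codon splitting. Internal coordinates are 0-based half-open; a feature
# wrapping the circular origin has end > genome length (interpreted on a
# virtually doubled sequence).

#' The 13 canonical protein-coding gene names of the insect mitogenome
#' @export
PCG_NAMES <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
               "nad5", "nad4", "nad4l", "nad6", "cob", "nad1")

#' Construct an annotated mitochondrial genome object
#'
#' @param accession identifier for the record.
#' @param sequence nucleotide string (IUPAC letters; case-insensitive,
#'   stored uppercase).
#' @param circular logical; is the molecule circular?
#' @param features data frame with columns `name`, `kind` (one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"`), `start`, `end`
#'   (0-based half-open; `end` may exceed the genome length only for
#'   features wrapping the origin of a circular molecule), `strand`
#'   (`"J"` majority / `"N"` minority) and `codon_start` (phase 0-2,
#'   `NA` for non-PCGs).
#' @return object of class `mito_genome`.
#' @export
mito_genome <- function(accession, sequence, circular = TRUE, features) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stopifnot(L > 0L)
  need <- c("name", "kind", "start", "end", "strand", "codon_start")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- features$start < 0L | features$start >= features$end |
    features$end > 2L * L
  if (any(bad)) {
    stop("invalid feature coordinates for: ",
         paste(features$name[bad], collapse = ", "))
  }
  if (any(features$end > L & !circular)) {
    stop("wrapped feature on a linear molecule")
  }
  if (!all(features$strand %in% c("J", "N"))) stop("strand must be 'J' or 'N'")
  if (!all(features$kind %in% c("PCG", "tRNA", "rRNA", "control_region"))) {
    stop("unknown feature kind")
  }
  # unidentified CDS features (name "CDS_<start>") are tolerated as PCGs
  pcg_bad <- features$kind == "PCG" & !(features$name %in% PCG_NAMES) &
    !grepl("^CDS_", features$name)
  if (any(pcg_bad)) {
    stop("PCG with non-canonical name: ",
         paste(unique(features$name[pcg_bad]), collapse = ", "))
  }
  structure(
    list(accession = accession, sequence = sequence,
         circular = isTRUE(circular),
         features = as.data.frame(features, stringsAsFactors = FALSE)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %s bp, %s, %d features\n",
              x$accession, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  cat("  ", paste(sprintf("%s:%d", c("PCG", "tRNA", "rRNA", "control_region"),
                          tabulate(factor(x$features$kind,
                                          c("PCG", "tRNA", "rRNA",
                                            "control_region")), 4)),
                  collapse = " "), "\n")
  invisible(x)
}

#' @export
genome_length <- function(genome) nchar(genome$sequence)

# Normalization table: GenBank spellings from many submitters -> canonical
# names. Matching is case-insensitive after stripping punctuation.
.gene_alias <- local({
  al <- list(
    cox1 = c("cox1", "coi", "co1", "coxi", "cytochromecoxidasesubuniti",
             "cytochromecoxidasesubunit1"),
    cox2 = c("cox2", "coii", "co2", "coxii", "cytochromecoxidasesubunitii",
             "cytochromecoxidasesubunit2"),
    cox3 = c("cox3", "coiii", "co3", "coxiii", "cytochromecoxidasesubunitiii",
             "cytochromecoxidasesubunit3"),
    cob = c("cob", "cytb", "cytochromeb", "cytochromebapoenzyme"),
    nad1 = c("nad1", "nd1", "nadhdehydrogenasesubunit1"),
    nad2 = c("nad2", "nd2", "nadhdehydrogenasesubunit2"),
    nad3 = c("nad3", "nd3", "nadhdehydrogenasesubunit3"),
    nad4 = c("nad4", "nd4", "nadhdehydrogenasesubunit4"),
    nad4l = c("nad4l", "nd4l", "nadhdehydrogenasesubunit4l"),
    nad5 = c("nad5", "nd5", "nadhdehydrogenasesubunit5"),
    nad6 = c("nad6", "nd6", "nadhdehydrogenasesubunit6"),
    atp6 = c("atp6", "atpase6", "atpsynthasef0subunit6"),
    atp8 = c("atp8", "atpase8", "atpsynthasef0subunit8"),
    rrnL = c("rrnl", "lrrna", "16s", "16srrna", "16sribosomalrna",
             "largesubunitribosomalrna", "rrn16"),
    rrnS = c("rrns", "srrna", "12s", "12srrna", "12sribosomalrna",
             "smallsubunitribosomalrna", "rrn12"),
    CR = c("cr", "controlregion", "atrichregion", "dloop",
           "putativecontrolregion")
  )
  # tRNAs: one- and three-letter forms; Leu/Ser paralogs by anticodon class.
  aa3 <- c(A = "ala", R = "arg", N = "asn", D = "asp", C = "cys", Q = "gln",
           E = "glu", G = "gly", H = "his", I = "ile", K = "lys", M = "met",
           F = "phe", P = "pro", T = "thr", W = "trp", Y = "tyr", V = "val")
  for (a in names(aa3)) {
    al[[paste0("trn", a)]] <- c(paste0("trn", tolower(a)),
                                paste0("trna", aa3[[a]]))
  }
  al$trnL1 <- c("trnl1", "trnlcun", "trnaleucun", "trnaleutag", "trnltag")
  al$trnL2 <- c("trnl2", "trnluur", "trnaleuuur", "trnaleutaa", "trnltaa")
  al$trnS1 <- c("trns1", "trnsagn", "trnaseragn", "trnasergct", "trnsgct",
                "trnstct", "trnasertct")
  al$trnS2 <- c("trns2", "trnsucn", "trnaserucn", "trnasertga", "trnstga")
  lut <- stats::setNames(rep(names(al), lengths(al)), unlist(al))
  lut
})

#' Normalize a GenBank gene label to the canonical name
#'
#' Maps the many submitter spellings (COX1/COI/cox1, l-rRNA/16S/rrnL,
#' trnL(uur)/tRNA-Leu, D-loop/control region, ...) to the canonical gene
#' names used throughout the package.
#'
#' @param raw character vector of labels as found in a GenBank record.
#' @return canonical names; `NA` where no alias matches.
#' @export
normalize_gene_name <- function(raw) {
  key <- tolower(gsub("[^A-Za-z0-9]", "", raw))
  out <- unname(.gene_alias[key])
  out[vapply(out, is.null, logical(1))] <- NA_character_
  unlist(out, use.names = FALSE)
}

#' Extract the coding-sense sequence of a feature
#'
#' Returns the nucleotide sequence of a feature in its coding orientation:
#' minority-strand (N) features are reverse-complemented, and features that
#' wrap the circular origin (end > genome length) are read across the
#' origin. Length of the result is `end - start`.
#'
#' @param genome a [mito_genome()].
#' @param feature a feature name, a row index into `genome$features`, or a
#'   list/one-row data frame with `start`, `end`, `strand`.
#' @return nucleotide string.
#' @export
extract_gene_sequence <- function(genome, feature) {
  f <- .resolve_feature(genome, feature)
  L <- genome_length(genome)
  if (f$end > 2L * L || f$start < 0L || f$start >= f$end) {
    stop("feature coordinates out of range: [", f$start, ", ", f$end, ")")
  }
  if (f$end > L && !genome$circular) stop("wrapped feature on linear genome")
  s <- if (f$end <= L) {
    substr(genome$sequence, f$start + 1L, f$end)
  } else {
    paste0(substr(genome$sequence, f$start + 1L, L),
           substr(genome$sequence, 1L, f$end - L))
  }
  if (identical(f$strand, "N")) s <- .revcomp(s)
  s
}

#' @keywords internal
.resolve_feature <- function(genome, feature) {
  ft <- genome$features
  if (is.character(feature) && length(feature) == 1L) {
    i <- which(ft$name == feature)
    if (length(i) == 0L) stop("no feature named '", feature, "'")
    feature <- i[1L]
  }
  if (is.numeric(feature) && length(feature) == 1L) {
    return(as.list(ft[feature, , drop = FALSE]))
  }
  if (is.data.frame(feature)) return(as.list(feature[1L, , drop = FALSE]))
  as.list(feature)
}

#' Split a nucleotide sequence into codons
#'
#' Drops `phase` leading bases (the GenBank `codon_start` offset), then
#' returns consecutive non-overlapping triplets plus the 0-2 base trailing
#' remnant (a truncated termination codon completed by polyadenylation in
#' mitochondrial transcripts).
#'
#' @param seq nucleotide string.
#' @param phase integer 0-2, leading bases to drop before the first codon.
#' @return list with `codons` (character vector) and `remnant` (string of
#'   length 0-2).
#' @export
codon_split <- function(seq, phase = 0L) {
  stopifnot(phase %in% 0:2)
  body <- substr(seq, phase + 1L, nchar(seq))
  n <- nchar(body)
  k <- n %/% 3L
  codons <- if (k > 0L) {
    substring(body, 3L * (seq_len(k) - 1L) + 1L, 3L * seq_len(k))
  } else character(0)
  list(codons = codons, remnant = substr(body, 3L * k + 1L, n))
}

# Coding-sense PCG bodies with the terminal stop removed. Returns a list of
# codon vectors (one per PCG, genome order). A trailing complete stop codon
# (TAA/TAG) and any truncated remnant are excluded.
#' @keywords internal
.pcg_codons <- function(genome, keep_stop = FALSE) {
  ft <- genome$features
  idx <- which(ft$kind == "PCG")
  out <- vector("list", length(idx))
  names(out) <- ft$name[idx]
  for (k in seq_along(idx)) {
    i <- idx[k]
    phase <- ft$codon_start[i]
    if (is.na(phase)) phase <- 0L
    cs <- codon_split(extract_gene_sequence(genome, i), phase)
    codons <- cs$codons
    if (!keep_stop && length(codons) &&
        codons[length(codons)] %in% c("TAA", "TAG")) {
      codons <- codons[-length(codons)]
    }
    attr(codons, "remnant") <- cs$remnant
    out[[k]] <- codons
  }
  out
}
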