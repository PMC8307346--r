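# GenBank parsing, coordinate conventions, sequence extraction and
# alignment I/O.

minimal_gb <- function(features, seq) {
  c(sprintf("LOCUS       TEST %d bp    DNA     circular   INV", nchar(seq)),
    "ACCESSION   TEST",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    features,
    "ORIGIN",
    sprintf("%9d %s", 1L, tolower(seq)),
    "//")
}

test_that("GenBank 1-based inclusive coordinates convert to 0-based half-open", {
  f <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(c("     CDS             1..9",
                          '                     /gene="cox1"'),
                        "ATGAAATAAGGG"), f)
  g <- read_genbank(f)
  expect_equal(g$features$start, 0L)
  expect_equal(g$features$end, 9L)
  expect_equal(g$features$strand, "J")
  expect_true(g$circular)
})

test_that("complement locations map to the minority strand", {
  f <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(c("     tRNA            complement(4..9)",
                          '                     /gene="trnW"'),
                        "ATGAAATAAGGG"), f)
  g <- read_genbank(f)
  expect_equal(g$features$strand, "N")
  expect_equal(g$features$start, 3L)
  expect_equal(g$features$end, 9L)
})

test_that("join across the origin becomes a wrapped interval", {
  f <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(c("     D-loop          join(10..12,1..3)",
                          '                     /gene="CR"'),
                        "ATGAAATAAGGG"), f)
  g <- read_genbank(f)
  expect_equal(g$features$start, 9L)
  expect_equal(g$features$end, 15L)  # 12 + 3
  expect_equal(extract_gene_sequence(g, 1L), "GGGATG")
})

test_that("unresolvable gene names warn and fall back to the feature key", {
  f <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(c("     tRNA            1..6",
                          '                     /gene="mystery99"'),
                        "ATGAAATAAGGG"), f)
  expect_warning(g <- read_genbank(f), "unresolvable")
  expect_equal(g$features$kind, "tRNA")
})

test_that("malformed records raise parse errors naming the problem line", {
  f <- tempfile(fileext = ".gb")
  writeLines(c("not a genbank file", "at all"), f)
  expect_error(read_genbank(f), "LOCUS")
  writeLines(minimal_gb(c("     CDS             what..ever",
                          '                     /gene="cox1"'),
                        "ATGAAATAAGGG"), f)
  expect_error(read_genbank(f), "line")
})

test_that("GenBank coordinate conversion round-trips on random locations", {
  set.seed(1)
  L <- 16000L
  for (i in 1:2000) {
    a <- sample.int(L - 1L, 1L)
    b <- sample(a:L, 1L)
    strand <- sample(c("J", "N"), 1L)
    loc <- sprintf("%d..%d", a, b)
    if (strand == "N") loc <- sprintf("complement(%s)", loc)
    p <- mitocomp:::.parse_location(loc, L)
    expect_equal(p$start + 1L, a)
    expect_equal(p$end, b)
    expect_equal(p$strand, strand)
  }
  # wrapped locations
  for (i in 1:200) {
    a <- sample.int(L - 1L, 1L)
    b <- sample.int(a - 1L, 1L)
    p <- mitocomp:::.parse_location(sprintf("join(%d..%d,1..%d)", a, L, b), L)
    expect_equal(p$start + 1L, a)
    expect_equal(p$end, L + b)
  }
})

test_that("extraction returns coding-sense sequence on either strand", {
  g <- mito_genome("X", "AAACCC", FALSE,
                   data.frame(name = c("trnA", "trnC"), kind = "tRNA",
                              start = c(0L, 3L), end = c(3L, 6L),
                              strand = c("J", "N"), codon_start = NA))
  expect_equal(extract_gene_sequence(g, 1L), "AAA")
  expect_equal(extract_gene_sequence(g, 2L), "GGG")
  # circular wrap on a doubled-sequence interval
  g2 <- mito_genome("X", "AACCGG", TRUE,
                    data.frame(name = "trnA", kind = "tRNA", start = 4L,
                               end = 8L, strand = "J", codon_start = NA))
  expect_equal(extract_gene_sequence(g2, 1L), "GGAA")
})

test_that("extraction is strand-symmetric under genome reverse complement", {
  set.seed(2)
  for (i in 1:50) {
    L <- sample(50:200, 1L)
    seq <- random_dna(L)
    a <- sample.int(L - 1L, 1L) - 1L
    b <- sample((a + 1L):L, 1L)
    strand <- sample(c("J", "N"), 1L)
    f1 <- data.frame(name = "trnA", kind = "tRNA", start = a, end = b,
                     strand = strand, codon_start = NA)
    g1 <- mito_genome("X", seq, FALSE, f1)
    # mirrored feature on the reverse-complemented genome
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    f2 <- f1
    f2$start <- L - b
    f2$end <- L - a
    f2$strand <- if (strand == "J") "N" else "J"
    g2 <- mito_genome("X", rc, FALSE, f2)
    expect_identical(extract_gene_sequence(g1, 1L),
                     extract_gene_sequence(g2, 1L))
  }
})

test_that("codon_split honours phase and returns the truncated remnant", {
  expect_equal(codon_split("ATGAAAT"),
               list(codons = c("ATG", "AAA"), remnant = "T"))
  expect_equal(codon_split("ATGAAA"),
               list(codons = c("ATG", "AAA"), remnant = ""))
  expect_equal(codon_split("CATGAAA", 1L),
               list(codons = c("ATG", "AAA"), remnant = ""))
  expect_equal(codon_split("", 0L), list(codons = character(0), remnant = ""))
})

test_that("extracted PCG lengths are consistent with the codon_split contract", {
  g <- synth_fixture()$genome
  ft <- g$features
  for (i in which(ft$kind == "PCG")) {
    s <- extract_gene_sequence(g, i)
    cs <- codon_split(s, ft$codon_start[i])
    expect_equal(nchar(s) %% 3L, nchar(cs$remnant) %% 3L)
    expect_equal(3L * length(cs$codons) + nchar(cs$remnant) +
                   ft$codon_start[i], nchar(s))
  }
})

test_that("aligned FASTA round-trips byte-exactly and rejects bad input", {
  rows <- c(tax1 = "ACGT-A", tax2 = "ACCTTA", tax3 = "ANGT-A")
  aln <- mito_alignment("g1", rows)
  f <- tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f, gene = "g1")
  expect_identical(back$rows, unname(rows))
  expect_identical(back$taxa, names(rows))

  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_alignment(f), "duplicate")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_alignment(f), "ragged")
  writeLines(c(">a", "ACGT"), f)
  expect_error(read_alignment(f), "2 taxa")
})

test_that("gene name normalization maps submitter spellings to canonical names", {
  expect_equal(normalize_gene_name(c("COX1", "COI", "cox1")),
               rep("cox1", 3))
  expect_equal(normalize_gene_name(c("l-rRNA", "16S ribosomal RNA")),
               rep("rrnL", 2))
  expect_equal(normalize_gene_name(c("tRNA-Leu(UUR)", "trnL2")),
               rep("trnL2", 2))
  expect_equal(normalize_gene_name("D-loop"), "CR")
  expect_true(is.na(normalize_gene_name("whatsit")))
})
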