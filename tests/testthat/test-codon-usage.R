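# Codon counting, RSCU under the invertebrate mitochondrial code, and
# start/stop tabulation.

test_that("the genetic code is table 5 (invertebrate mitochondrial)", {
  gc5 <- genetic_code_5()
  expect_equal(unname(gc5[c("AGA", "AGG", "ATA", "TGA")]),
               c("S", "S", "M", "W"))
  expect_equal(sort(names(gc5[gc5 == "*"])), c("TAA", "TAG"))
  expect_equal(sum(gc5[c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")] == "L"), 6)
})

test_that("count_codons pools PCGs, excludes stops, remnants and ambiguity", {
  g <- toy_genome()  # cox1 = ATG AAA TTC TAA (J); nad1 = ATT CCT TAA (N)
  cc <- count_codons(g)
  expect_equal(nrow(cc), 64L)
  expect_equal(cc$count[cc$codon == "AUG"], 1L)
  expect_equal(cc$count[cc$codon == "AAA"], 1L)
  expect_equal(cc$count[cc$codon == "UUC"], 1L)
  expect_equal(cc$count[cc$codon == "AUU"], 1L)
  expect_equal(cc$count[cc$codon == "CCU"], 1L)
  expect_equal(cc$count[cc$codon == "UAA"], 0L)  # stops never counted
  expect_equal(sum(cc$count), 5L)

  gn <- mito_genome("X", "ATGATNAAATAA", FALSE,
                    data.frame(name = "cox1", kind = "PCG", start = 0L,
                               end = 12L, strand = "J", codon_start = 0L))
  ccn <- count_codons(gn)
  expect_equal(sum(ccn$count), 2L)  # ATN codon dropped

  g_empty <- mito_genome("X", "AAAA", FALSE,
                         data.frame(name = "trnA", kind = "tRNA", start = 0L,
                                    end = 4L, strand = "J", codon_start = NA))
  expect_error(count_codons(g_empty), "PCG")
})

test_that("RSCU matches hand-evaluated examples", {
  base <- count_codons(toy_genome())
  base$count <- 0L
  leu <- c("UUA", "UUG", "CUU", "CUC", "CUA", "CUG")

  tab <- base
  tab$count[tab$codon %in% leu] <- 5L
  r <- rscu(tab)
  expect_equal(r$rscu[r$codon %in% leu], rep(1, 6))

  tab <- base
  tab$count[tab$codon %in% leu] <- 1L
  tab$count[tab$codon == "UUA"] <- 13L
  r <- rscu(tab)
  expect_equal(r$rscu[r$codon == "UUA"], 13 * 6 / 18)  # = 13/3

  tab <- base
  tab$count[tab$codon == "UUA"] <- 7L
  r <- rscu(tab)
  expect_equal(r$rscu[r$codon == "UUA"], 6)
  # untouched families are zero-flagged
  expect_true(all(r$family_unused[r$aa == "G"]))
  expect_equal(r$rscu[r$aa == "G"], rep(0, 4))
})

test_that("RSCU family sums equal family size and scale-invariance holds", {
  base <- count_codons(toy_genome())
  set.seed(4)
  for (i in 1:300) {
    tab <- base
    tab$count <- stats::rpois(64L, lambda = sample(c(0.5, 3, 20), 1))
    r <- rscu(tab)
    sums <- tapply(r$rscu, r$aa, sum)
    sizes <- tapply(r$family_size, r$aa, function(x) x[1])
    used <- !tapply(r$family_unused, r$aa, any)
    expect_equal(as.numeric(sums[used]), as.numeric(sizes[used]),
                 tolerance = 1e-9)
    expect_true(all(r$rscu <= r$family_size + 1e-9))
    # scale invariance
    tab2 <- tab
    tab2$count <- tab$count * 7L
    expect_equal(rscu(tab2)$rscu, r$rscu, tolerance = 1e-12)
  }
})

test_that("start/stop table flags truncated stops and non-ATN starts", {
  mk <- function(seq) {
    mito_genome("X", seq, FALSE,
                data.frame(name = "cox1", kind = "PCG", start = 0L,
                           end = nchar(seq), strand = "J", codon_start = 0L))
  }
  ss <- start_stop_table(mk("ATGAAATAA"))
  expect_equal(ss$start_codon, "ATG")
  expect_equal(ss$stop_codon, "TAA")
  expect_false(ss$stop_truncated)

  ss <- start_stop_table(mk("ATGAAAT"))
  expect_equal(ss$stop_codon, "T(truncated)")
  expect_true(ss$stop_truncated)
  expect_true(ss$start_is_ATN)

  ss <- start_stop_table(mk("GTGAAATAA"))
  expect_false(ss$start_is_ATN)
})

test_that("synthetic genomes use ATN starts and TAA/TAG or truncated stops", {
  ss <- start_stop_table(synth_fixture()$genome)
  expect_equal(nrow(ss), 13L)
  expect_true(all(ss$start_is_ATN))
  expect_true(all(ss$stop_codon %in%
                    c("TAA", "TAG", "T(truncated)", "TA(truncated)")))
})
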