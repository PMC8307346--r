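# Synthetic genome and alignment generators: determinism, planted ground
# truth, spec validation and limit behavior.

test_that("generators are seed-deterministic (byte-identical output)", {
  g1 <- generate_genome(synthetic_genome_spec(seed = 3L))
  g2 <- generate_genome(synthetic_genome_spec(seed = 3L))
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$genome$features, g2$genome$features)
  expect_identical(g1$truth$repeats, g2$truth$repeats)
  g3 <- generate_genome(synthetic_genome_spec(seed = 4L))
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))

  a1 <- evolve_k2p(strrep("ACGT", 100), 3, 0.1, seed = 9L)
  a2 <- evolve_k2p(strrep("ACGT", 100), 3, 0.1, seed = 9L)
  expect_identical(a1$rows, a2$rows)
  c1 <- evolve_codons(strrep("GGTATT", 50), 3, 0.5, seed = 9L)
  c2 <- evolve_codons(strrep("GGTATT", 50), 3, 0.5, seed = 9L)
  expect_identical(c1$rows, c2$rows)
})

test_that("the canonical 37-gene layout is produced with both strands", {
  g <- synth_fixture()$genome
  ft <- g$features
  expect_equal(sum(ft$kind == "PCG"), 13L)
  expect_equal(sum(ft$kind == "tRNA"), 22L)
  expect_equal(sum(ft$kind == "rRNA"), 2L)
  expect_equal(sum(ft$kind == "control_region"), 1L)
  expect_equal(sum(ft$strand == "N"), 14L)  # 4 PCGs + 8 tRNAs + 2 rRNAs
  expect_true(genome_length(g) > 16000 && genome_length(g) < 18000)
})

test_that("realized composition hits the target within 0.5% per base", {
  for (seed in c(1L, 23L, 99L)) {
    spec <- synthetic_genome_spec(seed = seed)
    g <- generate_genome(spec)$genome
    bc <- count_bases(g$sequence)
    tot <- bc$nA + bc$nC + bc$nG + bc$nT
    real <- c(bc$nA, bc$nC, bc$nG, bc$nT) / tot
    expect_lt(max(abs(real - spec$composition)), 0.005)
  }
  # a different target is also honoured
  spec <- synthetic_genome_spec(
    composition = c(A = 0.38, C = 0.16, G = 0.12, T = 0.34), seed = 5L)
  g <- generate_genome(spec)$genome
  bc <- count_bases(g$sequence)
  tot <- bc$nA + bc$nC + bc$nG + bc$nT
  expect_lt(max(abs(c(bc$nA, bc$nC, bc$nG, bc$nT) / tot - spec$composition)),
            0.005)
})

test_that("generated GenBank round-trips losslessly through the reader", {
  gt <- synth_fixture()
  f <- tempfile(fileext = ".gb")
  write_genbank(gt$genome, f)
  back <- read_genbank(f)
  expect_identical(back$sequence, gt$genome$sequence)
  expect_identical(back$features, gt$genome$features)
  expect_identical(back$circular, TRUE)
})

test_that("infeasible plans are rejected as spec errors", {
  expect_error(synthetic_genome_spec(
    composition = c(A = .5, C = .2, G = .2, T = .2)), "sum to 1")
  expect_error(synthetic_genome_spec(
    junctions = c("trnI|trnQ" = -70)), "exceeds gene length")
  expect_error(synthetic_genome_spec(
    junctions = c("atp8|atp6" = -2)), "4 bp")
  expect_error(synthetic_genome_spec(
    planted_repeats = list(c(500, 3)), cr_length = 1200L), "exceed")
  expect_error(generate_genome(synthetic_genome_spec(
    junctions = c("cox1|trnW" = 5))), "consecutive")
})

test_that("K2P evolution: d = 0 is the identity and kappa -> Inf kills transversions", {
  root <- strrep("ACGT", 500)
  a <- evolve_k2p(root, 4, 0, seed = 2L)
  expect_true(all(a$rows == root))
  b <- evolve_k2p(root, 2, 0.3, kappa = Inf, seed = 2L)
  d <- k2p(b$rows[1], b$rows[2])
  expect_equal(attr(d, "Q"), 0)
  expect_gt(attr(d, "P"), 0)
})

test_that("codon evolution with omega = 0 conserves the protein exactly", {
  root <- random_coding_sequence(200)
  a <- evolve_codons(root, 4, 0, prop_rate = 0.2, seed = 6L)
  prot <- function(s) paste(translate_codons(codon_split(s)$codons),
                            collapse = "")
  expect_true(all(vapply(a$rows, prot, character(1)) == prot(root)))
  expect_false(all(a$rows == root))  # but synonymous changes happened
})

test_that("codon evolution with omega = 1 gives Ka comparable to Ks", {
  set.seed(22)
  root <- random_coding_sequence(400)
  kas <- c(); kss <- c()
  for (r in 1:6) {
    a <- evolve_codons(root, 2, 1, prop_rate = 0.15, seed = 800L + r)
    rec <- ng86_kaks(a$rows[1], a$rows[2])
    kas <- c(kas, rec$Ka); kss <- c(kss, rec$Ks)
  }
  expect_equal(mean(kas) / mean(kss), 1, tolerance = 0.25)
})

test_that("no synthetic PCG contains an internal stop codon", {
  g <- synth_fixture()$genome
  gc5 <- genetic_code_5()
  for (i in which(g$features$kind == "PCG")) {
    codons <- codon_split(extract_gene_sequence(g, i))$codons
    body <- codons[-length(codons)]
    expect_false(any(gc5[body] == "*"),
                 info = g$features$name[i])
  }
})
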