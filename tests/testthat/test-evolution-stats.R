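# K2P distances, nucleotide diversity, sliding windows and NG86 Ka/Ks.

test_that("K2P matches the closed form and flags saturation", {
  expect_equal(as.numeric(k2p("ACGT", "ACGT")), 0)
  a <- paste0(strrep("A", 85), strrep("G", 10), strrep("C", 5))
  b <- strrep("A", 100)
  expect_equal(as.numeric(k2p(a, b)), 0.17018, tolerance = 1e-4)
  expect_equal(attr(k2p(a, b), "P"), 0.10)
  expect_equal(attr(k2p(a, b), "Q"), 0.05)
  # P = 0.5, Q = 0: log of a non-positive number -> saturation sentinel
  sat <- k2p(strrep("A", 10), paste0(strrep("G", 5), strrep("A", 5)))
  expect_true(is.na(sat))
  expect_true(attr(sat, "saturated"))
})

test_that("K2P uses pairwise deletion and agrees with ape on random pairs", {
  d <- k2p("AC-GTN", "ACCGTA")
  expect_equal(attr(d, "n_sites"), 4L)
  set.seed(10)
  root <- random_dna(2000, comp = c(A = .25, C = .25, G = .25, T = .25))
  for (i in 1:20) {
    a <- evolve_k2p(root, 2, stats::runif(1, 0.01, 0.3),
                    kappa = stats::runif(1, 0.5, 5), seed = 100L + i)
    m <- rbind(strsplit(tolower(a$rows[1]), "")[[1]],
               strsplit(tolower(a$rows[2]), "")[[1]])
    ape_d <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
    expect_equal(as.numeric(k2p(a$rows[1], a$rows[2])), ape_d,
                 tolerance = 1e-10)
  }
})

test_that("K2P dominates the p-distance and converges to it near zero", {
  set.seed(11)
  root <- random_dna(5000)
  for (d in c(0.005, 0.05, 0.2, 0.35)) {
    a <- evolve_k2p(root, 2, d / 2, kappa = 2, seed = 200L + round(1000 * d))
    v1 <- strsplit(a$rows[1], "")[[1]]
    v2 <- strsplit(a$rows[2], "")[[1]]
    p_dist <- mean(v1 != v2)
    k <- as.numeric(k2p(a$rows[1], a$rows[2]))
    expect_gte(k, p_dist)
    if (d == 0.005) expect_equal(k, p_dist, tolerance = 0.05)
  }
})

test_that("the K2P estimator recovers planted distances within 2 SE", {
  set.seed(12)
  root <- random_dna(10000)
  for (d in c(0.05, 0.2, 0.4)) {
    est <- vapply(1:25, function(r) {
      a <- evolve_k2p(root, 2, d / 2, kappa = 2,
                      seed = 300L + round(1000 * d) + r)
      as.numeric(k2p(a$rows[1], a$rows[2]))
    }, numeric(1))
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - d), 2 * se)
  }
})

test_that("mean pairwise K2P behaves and errors when all pairs saturate", {
  aln <- mito_alignment("g", c(a = "ACGTACGT", b = "ACGTACGT",
                               c = "ACGTACGT"))
  expect_equal(as.numeric(gene_mean_k2p(aln)), 0)
  sat <- mito_alignment("g", c(a = strrep("A", 10),
                               b = paste0(strrep("G", 5), strrep("A", 5))))
  expect_error(gene_mean_k2p(sat), "saturation")
})

test_that("Pi matches pair enumeration", {
  a <- strrep("A", 100)
  b <- paste0("C", strrep("A", 99))
  expect_equal(nucleotide_diversity(mito_alignment("g", c(x = a, y = b))),
               0.01)
  # three sequences with pairwise p-distances 0.01, 0.02, 0.03 -> mean 0.02
  c_ <- paste0("AGG", strrep("A", 97))  # vs a: 0.02; vs b: sites 1,2,3 -> 0.03
  aln <- mito_alignment("g", c(x = a, y = b, z = c_))
  expect_equal(nucleotide_diversity(aln), 0.02)
  expect_equal(nucleotide_diversity(mito_alignment("g", c(x = a, y = a))), 0)
})

test_that("Pi of a concatenation is the usable-site-weighted mean", {
  set.seed(13)
  a1 <- evolve_k2p(random_dna(400), 3, 0.05, seed = 31)
  a2 <- evolve_k2p(random_dna(600), 3, 0.15, seed = 32)
  cc <- aln_concat(list(a1, a2))
  expect_equal(nucleotide_diversity(cc),
               (400 * nucleotide_diversity(a1) +
                  600 * nucleotide_diversity(a2)) / 1000,
               tolerance = 1e-12)
})

test_that("sliding windows enumerate full windows only", {
  set.seed(14)
  aln <- evolve_k2p(random_dna(300), 3, 0.1, seed = 33)
  prof <- sliding_window_pi(aln, window = 200L, step = 20L)
  expect_equal(prof$start, seq(0L, 100L, by = 20L))
  expect_equal(nrow(prof), 6L)
  expect_equal(prof$midpoint, prof$start + 100)
  # window = alignment length reduces to whole-gene Pi
  whole <- sliding_window_pi(aln, window = 300L, step = 20L)
  expect_equal(nrow(whole), 1L)
  expect_equal(whole$pi, nucleotide_diversity(aln))
  # constant alignment -> all-zero profile
  flat <- mito_alignment("g", c(a = strrep("ACGT", 75),
                                b = strrep("ACGT", 75)))
  expect_true(all(sliding_window_pi(flat)$pi == 0))
  expect_warning(short <- sliding_window_pi(aln, window = 400L), "shorter")
  expect_equal(nrow(short), 1L)
})

test_that("NG86 matches hand-derived site and difference counts", {
  r0 <- ng86_kaks("ATGATT", "ATGATT")
  expect_equal(c(r0$Sd, r0$Nd, r0$Ka, r0$Ks), c(0, 0, 0, 0))

  # 10 Gly codons, one synonymous third-position change
  r <- ng86_kaks(strrep("GGT", 10), paste0("GGC", strrep("GGT", 9)))
  expect_equal(r$S, 10)
  expect_equal(r$Sd, 1)
  expect_equal(r$ps, 0.1)
  expect_equal(r$Ks, 0.10732, tolerance = 1e-4)
  expect_equal(r$Ka, 0)
  expect_equal(r$S + r$N, 3 * r$n_codons, tolerance = 1e-6)

  # two-position codon pair: pathway-averaged split over the 2 orders
  r2 <- ng86_kaks("TTA", "CTC")
  o <- ng86_count_oracle("TTA", "CTC")
  expect_equal(r2$Sd, o[["Sd"]], tolerance = 1e-12)
  expect_equal(r2$Nd, o[["Nd"]], tolerance = 1e-12)
  expect_equal(r2$Sd + r2$Nd, 2, tolerance = 1e-12)
})

test_that("NG86 pathway counts equal the brute-force oracle on random pairs", {
  set.seed(15)
  for (i in 1:120) {
    a <- random_coding_sequence(30)
    b <- random_coding_sequence(30)
    r <- ng86_kaks(a, b)
    ca <- codon_split(a)$codons
    cb <- codon_split(b)$codons
    o <- rowSums(mapply(ng86_count_oracle, ca, cb))
    expect_equal(r$Sd, o[["Sd"]], tolerance = 1e-9)
    expect_equal(r$Nd, o[["Nd"]], tolerance = 1e-9)
    expect_equal(r$S + r$N, 90, tolerance = 1e-6)
  }
})

test_that("codon-wise pairwise deletion drops gapped and ambiguous codons", {
  r <- ng86_kaks("ATG---ATT", "ATGAAAATN")
  expect_equal(r$n_codons, 1L)
  expect_error(ng86_kaks("AT", "AT"), "multiple of 3")
  expect_error(ng86_kaks("---", "AAA"), "usable")
})

test_that("purely synonymous variation yields mean omega 0", {
  base <- strrep("GGT", 40)
  rows <- c(a = base,
            b = paste0("GGC", substr(base, 4, 120)),
            c = paste0("GGAGGA", substr(base, 7, 120)))
  mk <- gene_mean_kaks(mito_alignment("g", rows))
  expect_equal(mk$mean_omega, 0)
  expect_equal(mk$mean_ka, 0)
  expect_gt(mk$mean_ks, 0)
})

test_that("gene_mean_kaks recovers a planted omega", {
  set.seed(16)
  root <- random_coding_sequence(300)
  est <- vapply(1:8, function(r) {
    a <- evolve_codons(root, 4, 0.2, prop_rate = 0.15, seed = 400L + r)
    gene_mean_kaks(a)$mean_omega
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.2), max(3 * se, 0.01))
})

test_that("genes simulated under purifying selection give omega < 1", {
  set.seed(17)
  oms <- vapply(c(0.1, 0.3, 0.5), function(om) {
    a <- evolve_codons(random_coding_sequence(200), 4, om,
                       prop_rate = 0.12, seed = 500L + round(100 * om))
    gene_mean_kaks(a)$mean_omega
  }, numeric(1))
  expect_true(all(oms < 1))
  expect_lt(mean(oms), 1)
})
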