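test_that("tail detection follows the poly-A / poly-GA / poly-X precedence", {
  expect_identical(detect_tail("GGAGQGAAAAA")$kind, "poly_A")
  expect_identical(detect_tail("AAAAGAGAGA")$kind, "poly_GA")
  expect_identical(detect_tail("GPGPQVSVVSTTVS")$kind, "poly_X")
  expect_identical(detect_tail("GGLGGSGGSGGR")$kind, "none")
  expect_identical(detect_tail("QQPSSSVAISL")$kind, "none")
  expect_identical(detect_tail("AAAAAA"), list(kind = "poly_A",
                                               seq = "AAAAAA"))
})

test_that("motif scanning records the quoted Caerostris cases", {
  u1 <- scan_motifs("GPGPQGPGPQVSVVSTTVS", spidroin_grammars("MaSp4"))
  core <- u1$motif_hits[u1$motif_hits$kind == "core", ]
  expect_identical(core$start, c(0L, 5L))
  expect_identical(unique(core$motif), "GPGPQ")
  expect_identical(u1$tail_kind, "poly_X")
  expect_identical(u1$tail_seq, "VSVVSTTVS")

  u2 <- scan_motifs("GGLGGSGGSGGR", spidroin_grammars("MaSp5"))
  expect_setequal(u2$motif_hits$motif, c("GGLGGSG", "GSGGR"))
  expect_identical(u2$tail_kind, "none")

  u3 <- scan_motifs("AAAAAA", spidroin_grammars("MaSp2"))
  expect_identical(nrow(u3$motif_hits), 0L)
  expect_identical(u3$tail_kind, "poly_A")
})

test_that("family classification follows repeat content over NTD clade", {
  units4 <- rep("GPGPQGPGSGQPYGPGPQLGVSVVSTTVS", 5)
  cl <- classify_family(units4, ntd_assignment = "MaSp2")
  expect_identical(cl$family, "MaSp4")
  expect_false(cl$conflict)   # MaSp4 sits inside the MaSp2 clade

  cl3 <- classify_family(rep("GSGGSGGRGGYGSGSGGRGGYQAAAAA", 4))
  expect_identical(cl3$family, "MaSp3")

  clB <- classify_family(rep("GGAGGAGGYGQGGYGGAAAAGAGAGA", 4),
                         ntd_assignment = "MiSp1B")
  expect_true(clB$family %in% c("MiSp1B", "MiSp1D"))
  expect_false(clB$conflict)

  # a real clade conflict is flagged but repeat content wins
  clx <- classify_family(units4, ntd_assignment = "Flag")
  expect_identical(clx$family, "MaSp4")
  expect_true(clx$conflict)

  cl0 <- classify_family(list())
  expect_identical(cl0$family, "other")
  expect_true(all(cl0$scores == 0))
})

test_that("generated genes classify back to their family for every grammar", {
  for (fam in names(spidroin_grammars())) {
    g <- build_gene(fam, 8, 40, seed = 3)
    cl <- classify_family(g$repeats, ntd_assignment = fam)
    expect_identical(cl$family, fam)
    expect_false(cl$conflict)
  }
})

test_that("repeat decomposition recovers constructed tandem arrays", {
  flank1 <- random_protein(50, seed = 201)
  flank2 <- random_protein(50, seed = 202)
  prot <- paste0(flank1, strrep("GPGSQGPGSQAAAAAA", 6), flank2)
  units <- decompose_repeats(prot, 5, 60)
  expect_length(units, 6)
  expect_true(all(vapply(units, function(u) nchar(u$aa_seq), 1L) == 16L))
  # boundaries within one period of the construction
  all_aa <- paste(vapply(units, `[[`, "", "aa_seq"), collapse = "")
  expect_gte(nchar(gsub("[^A]", "", all_aa)), 6 * 5)

  units_ga <- decompose_repeats(strrep("GA", 30), 2, 30)
  expect_length(units_ga, 30)
  expect_identical(unique(vapply(units_ga, `[[`, "", "aa_seq")), "GA")

  expect_error(decompose_repeats("GAGA", 5, 60), "period_min")
})

test_that("random proteins decompose to nothing", {
  empties <- silkforge:::with_seed(203L, vapply(1:50, function(i) {
    p <- paste0(sample(AA, 300, replace = TRUE), collapse = "")
    length(decompose_repeats(p, 5, 100)) == 0
  }, logical(1)))
  expect_true(all(empties))
})

test_that("decomposition is shift-stable under a random prefix", {
  core <- strrep("GPGGAGPGGYQQSAAAAA", 8)
  base <- decompose_repeats(paste0(random_protein(30, seed = 204), core,
                                   random_protein(30, seed = 205)), 5, 60)
  shifted <- decompose_repeats(paste0(random_protein(55, seed = 206), core,
                                      random_protein(30, seed = 207)), 5, 60)
  expect_identical(length(base), length(shifted))
  expect_identical(nchar(base[[1]]$aa_seq), nchar(shifted[[1]]$aa_seq))
})

test_that("composition statistics are exact and flag CRPs", {
  r <- composition_stats("CAAAAAAAAA", crp_threshold = 0.05)
  expect_equal(r$cys_fraction, 0.10)
  expect_true(r$is_crp)

  r2 <- composition_stats("AAAA")
  expect_equal(unname(r2$fractions[["A"]]), 1.0)
  expect_false(r2$is_crp)

  p <- random_protein(200, seed = 208)
  r3 <- composition_stats(p)
  expect_equal(sum(r3$fractions), 1.0)
  ch <- strsplit(p, "")[[1]]
  for (a in unique(ch))
    expect_equal(unname(r3$fractions[[a]]), sum(ch == a) / 200)
  expect_error(composition_stats("ACGB"), "unknown residue.*B")
})

test_that("SpiCE designation ranks expressed non-spidroins", {
  shares <- c(MaSp1 = 0.5, s1 = 0.2, s2 = 0.15, s3 = 0.08, s4 = 0.05,
              s5 = 0.02)
  is_sp <- c(MaSp1 = TRUE, s1 = FALSE, s2 = FALSE, s3 = FALSE, s4 = FALSE,
             s5 = FALSE)
  tpms <- c(MaSp1 = 1000, s1 = 50, s2 = 0.5, s3 = 20, s4 = 10, s5 = 5)
  expect_identical(designate_spice(shares, is_sp, tpms),
                   c("s1", "s3", "s4", "s5"))
})
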