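test_that("terminal seeds reach the self-score ceiling on exact matches", {
  doms <- terminal_domains()
  ntd <- doms[["MaSp3_NTD"]]
  ctg <- silkforge:::with_seed(5L, silkforge:::reverse_translate(ntd))
  self <- Biostrings::score(Biostrings::pairwiseAlignment(
    ntd, ntd, type = "local", substitutionMatrix = silkforge:::blosum62(),
    gapOpening = 10, gapExtension = 1))
  seeds <- find_terminal_seeds(c(utg1 = ctg), doms["MaSp3_NTD"],
                               min_score = 100)
  top <- seeds[1, ]
  expect_equal(top$score, self)
  expect_identical(top$strand, "+")
  expect_identical(top$frame, 0L)
  expect_identical(c(top$hit_start, top$hit_end), c(0L, nchar(ctg)))

  # reverse complement: same score, '-' strand, coordinates still index the
  # hit on the forward strand of the contig
  seeds_rc <- find_terminal_seeds(c(utg1 = revcomp(ctg)), doms["MaSp3_NTD"],
                                  min_score = 100)
  top_rc <- seeds_rc[1, ]
  expect_equal(top_rc$score, self)
  expect_identical(top_rc$strand, "-")
  sub <- substr(top_rc$contig_seq, top_rc$hit_start + 1, top_rc$hit_end)
  expect_identical(translate_nt(revcomp(sub)), ntd)
})

test_that("random contigs produce no seeds at half the self-score", {
  doms <- terminal_domains()[c("MaSp1_NTD", "Flag_CTD")]
  half <- min(vapply(doms, function(d) Biostrings::score(
    Biostrings::pairwiseAlignment(d, d, type = "local",
                                  substitutionMatrix = silkforge:::blosum62(),
                                  gapOpening = 10, gapExtension = 1)),
    numeric(1))) / 2
  hits <- 0L
  silkforge:::with_seed(77L, {
    for (i in 1:100) {
      ctg <- silkforge:::random_dna(1000)
      s <- find_terminal_seeds(c(u = ctg), doms, min_score = half)
      hits <- hits + nrow(s)
    }
  })
  expect_identical(hits, 0L)
})

test_that("repeat-boundary detection localises the junction", {
  unit <- random_dna_str(30, seed = 51)
  lead <- random_dna_str(600, seed = 52)
  seqd <- paste0(lead, strrep(unit, 6))
  b <- detect_repeat_boundary(seqd, window = 60, period_max = 30)
  expect_false(is.null(b))
  expect_lte(abs(as.integer(b) - 600), 30)
  expect_identical(attr(b, "period"), 30L)

  expect_identical(as.integer(detect_repeat_boundary(
    strrep(unit, 6), window = 60, period_max = 30)), 0L)
  expect_error(detect_repeat_boundary(seqd, window = 50, period_max = 30),
               "2 \\* period_max")
})

test_that("random sequence shows no spurious periodicity", {
  nulls <- silkforge:::with_seed(53L, vapply(1:50, function(i)
    is.null(detect_repeat_boundary(silkforge:::random_dna(2000),
                                   window = 300, period_max = 150)),
    logical(1)))
  expect_true(all(nulls))
})

test_that("extension reproduces a unique region up to the repeat boundary", {
  unique_part <- random_dna_str(600, seed = 61)
  unit <- random_dna_str(90, seed = 62)
  src <- paste0(unique_part, strrep(unit, 8))
  short <- simulate_short_reads(src, 40, 150, 0, seed = 63)
  seed <- list(contig_seq = substr(src, 1, 200), strand = "+")
  cand <- extend_seed(seed, short, anchor_k = 51, min_depth = 5,
                      min_frac = 0.8, window = 180, period_max = 90)
  expect_identical(cand$halted_reason, "repeat_boundary")
  expect_lte(abs(cand$boundary_pos - 600), 51 + 1)
  span <- substr(cand$consensus, 1, min(nchar(cand$consensus), nchar(src)))
  expect_identical(span, substr(src, 1, nchar(span)))
  # PWM consistency on every extended column
  expect_true(all(cand$support$depth >= 5))
  expect_true(all(cand$support$max_frac >= 0.8))
})

test_that("a coverage gap halts extension with no_support", {
  src <- random_dna_str(4000, seed = 71)
  # reads only over the first half
  short <- simulate_short_reads(substr(src, 1, 2000), 40, 150, 0, seed = 72)
  seed <- list(contig_seq = substr(src, 1, 300), strand = "+")
  cand <- extend_seed(seed, short, window = 300, period_max = 150)
  expect_identical(cand$halted_reason, "no_support")
  expect_lte(nchar(cand$consensus), 2000)
  expect_gte(nchar(cand$consensus), 1900)
})

test_that("extension is orientation-symmetric on error-free input", {
  unique_part <- random_dna_str(500, seed = 81)
  unit <- random_dna_str(60, seed = 82)
  src <- paste0(strrep(unit, 6), revcomp(unique_part))
  # seed sits in the unique region; extending 5' on the forward orientation
  # must equal the reverse complement of extending 3' on the flipped seed
  short <- simulate_short_reads(src, 40, 150, 0, seed = 83)
  sfwd <- list(contig_seq = substr(src, nchar(src) - 299, nchar(src)),
               strand = "+")
  srev <- list(contig_seq = revcomp(sfwd$contig_seq), strand = "+")
  c5 <- extend_seed(sfwd, short, direction = "5p", window = 120,
                    period_max = 60)
  c3 <- extend_seed(srev, short, direction = "3p", window = 120,
                    period_max = 60)
  expect_identical(c5$consensus, c3$consensus)
  expect_identical(c5$halted_reason, c3$halted_reason)
})

test_that("end-to-end recovery on the reference synthetic spidroin", {
  gene <- study_gene(seed = 5)
  src <- study_source(gene, seed = 105)
  short <- simulate_short_reads(src, 50, 150, 0, seed = 106)
  cands <- assemble_candidates(short)
  expect_identical(cands$n$halted_reason, "repeat_boundary")
  expect_identical(cands$c$halted_reason, "repeat_boundary")
  expect_identical(cands$n$boundary_period, 120L)
  expect_identical(identity_vs(cands$n$consensus, src), 1)
  expect_identical(identity_vs(cands$c$consensus, src), 1)
  # union of N-side candidate, repeat unit and C-side candidate covers the
  # gene: the two candidates flank a 120 nt unit detected in both
  expect_gte(nchar(cands$n$consensus) + nchar(cands$c$consensus), 1500)
})
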