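make_long_set <- function(seqs, ids = sprintf("lr%03d", seq_along(seqs))) {
  read_set(data.frame(id = ids, seq = seqs, qual = NA_character_,
                      mate = NA_character_, stringsAsFactors = FALSE),
           platform = "long")
}

test_that("trusted-spectrum correction repairs isolated substitutions", {
  src <- random_dna_str(2000, seed = 91)
  short <- simulate_short_reads(src, 30, 100, 0, seed = 92)
  # single substitution mid-read
  ch <- strsplit(src, "")[[1]]
  pos <- 1000L
  ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  mutated <- paste0(ch, collapse = "")
  long <- make_long_set(c(mutated, src))
  fixed <- correct_long_reads(long, short, k = 15, min_count = 2)
  expect_identical(fixed$reads$seq[1], src)   # repaired
  expect_identical(fixed$reads$seq[2], src)   # fixed point
  expect_identical(nrow(fixed$reads), nrow(long$reads))
})

test_that("ambiguous repairs are left untouched", {
  # two versions of the same locus in the trusted spectrum differing at one
  # base -> an error there has two valid single-base repairs
  base <- random_dna_str(400, seed = 93)
  alt1 <- base
  substr(alt1, 200, 200) <- "A"
  alt2 <- base
  substr(alt2, 200, 200) <- "C"
  short <- c(rep(substring(alt1, seq(1, 301, 20), seq(100, 400, 20)), 2),
             rep(substring(alt2, seq(1, 301, 20), seq(100, 400, 20)), 2))
  broken <- base
  substr(broken, 200, 200) <- "T"
  stopifnot(!grepl("T", substr(alt1, 200, 200)))
  long <- make_long_set(broken)
  fixed <- correct_long_reads(long, short, k = 15, min_count = 2)
  expect_identical(substr(fixed$reads$seq[1], 200, 200), "T")
})

test_that("candidates embedded in long reads map exactly", {
  cand <- random_dna_str(500, seed = 94)
  lead <- random_dna_str(4000, seed = 95)
  tail <- random_dna_str(5500, seed = 96)
  read <- paste0(lead, cand, tail)
  long <- make_long_set(read)
  sup <- map_candidate(cand, long, seed_k = 15, min_identity = 0.9)
  expect_identical(nrow(sup), 1L)
  expect_equal(sup$identity, 1.0)
  expect_equal(c(sup$read_start, sup$read_end), c(4000, 4500))
  expect_identical(sup$strand, "+")
  expect_error(map_candidate(substr(cand, 1, 10), long, seed_k = 15),
               "shorter than seed_k")
})

test_that("mapping is strand-symmetric with mirrored coordinates", {
  cand <- random_dna_str(500, seed = 94)
  read <- paste0(random_dna_str(2000, seed = 97), cand,
                 random_dna_str(1500, seed = 98))
  sup_f <- map_candidate(cand, make_long_set(read), 15, 0.9)
  sup_r <- map_candidate(cand, make_long_set(revcomp(read)), 15, 0.9)
  expect_identical(sup_r$strand, "-")
  expect_equal(sup_r$identity, sup_f$identity)
  L <- nchar(read)
  expect_identical(sup_r$read_start, L - sup_f$read_end)
  expect_identical(sup_r$read_end, L - sup_f$read_start)
})

test_that("noisy embeddings map with the dialled-down identity", {
  cand <- random_dna_str(600, seed = 99)
  noisy_copy <- function(seq, e) {
    ch <- strsplit(seq, "")[[1]]
    ev <- sample(c("m", "s", "i", "d"), length(ch), TRUE,
                 prob = c(1 - e, 0.6 * e, 0.2 * e, 0.2 * e))
    out <- ch
    for (j in which(ev == "s"))
      out[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[sample.int(3, 1)]
    for (j in which(ev == "i"))
      out[j] <- paste0(out[j], sample(c("A", "C", "G", "T"), 1))
    out[ev == "d"] <- ""
    paste0(out, collapse = "")
  }
  idents <- silkforge:::with_seed(100L, vapply(1:20, function(i) {
    read <- noisy_copy(paste0(silkforge:::random_dna(3000), cand,
                              silkforge:::random_dna(3000)), 0.05)
    sup <- map_candidate(cand, make_long_set(read), 15, 0.85)
    if (nrow(sup)) sup$identity[1] else NA_real_
  }, numeric(1)))
  idents <- idents[!is.na(idents)]
  expect_gte(length(idents), 18)
  expect_true(all(idents > 0.88 & idents < 0.99))
})

test_that("reads that do not span both termini are never full length", {
  n_cand <- random_dna_str(400, seed = 101)
  c_cand <- random_dna_str(400, seed = 103)
  readA <- paste0(n_cand, random_dna_str(1000, seed = 104))   # N only
  readB <- paste0(random_dna_str(1000, seed = 105), c_cand)   # C only
  long <- make_long_set(c(readA, readB))
  sup <- flag_full_length(map_candidate(n_cand, long, name = "N"),
                          map_candidate(c_cand, long, name = "C"))
  expect_true(all(!sup$full_length))
  # and a read spanning both, in order, is full length on both rows
  readAB <- paste0(n_cand, random_dna_str(600, seed = 106), c_cand)
  long2 <- make_long_set(readAB)
  sup2 <- flag_full_length(map_candidate(n_cand, long2, name = "N"),
                           map_candidate(c_cand, long2, name = "C"))
  expect_true(all(sup2$full_length))
})

test_that("repeat-unit counting tiles greedily left to right", {
  unit <- random_dna_str(100, seed = 111)
  expect_identical(count_repeat_units(strrep(unit, 7), unit, 0.9), 7L)
  expect_identical(count_repeat_units(random_dna_str(700, seed = 112),
                                      unit, 0.9), 0L)
  expect_error(count_repeat_units("ACGT", "ACGTACGTACGTACG", 0.9),
               "at least 20 nt")
  # 3% errors over 10 seeded replicates still count 7
  counts <- silkforge:::with_seed(113L, vapply(1:10, function(i) {
    seg <- silkforge:::apply_substitutions(strrep(unit, 7), 0.03)
    count_repeat_units(seg, unit, 0.9)
  }, integer(1)))
  expect_true(all(counts == 7L))
})

test_that("modal repeat count recovers the architecture across sizes", {
  for (R in c(4L, 8L)) {
    gene <- build_gene("MiSp1B", R, 40, seed = 120 + R)
    src <- study_source(gene, seed = 130 + R, flank = 200)
    short <- simulate_short_reads(src, 40, 150, 0, seed = 140 + R)
    long <- simulate_long_reads(src, 12, 5000, 0.08, seed = 150 + R)
    corrected <- correct_long_reads(long, short, 15, 2)
    unit_nt <- substr(gene$cds_nt, 451, 570)   # NTD is 150 aa = 450 nt
    n_side <- paste0(substr(src, 1, 200 + 450))
    c_side <- substr(src, nchar(src) - 200 - 300 + 1, nchar(src))
    sup <- flag_full_length(
      map_candidate(n_side, corrected, 15, 0.75, name = "N"),
      map_candidate(c_side, corrected, 15, 0.75, name = "C"))
    full <- unique(sup$read_id[sup$full_length])
    counts <- integer(0)
    for (id in full) {
      a <- sup[sup$read_id == id & sup$candidate_name == "N", ][1, ]
      b <- sup[sup$read_id == id & sup$candidate_name == "C", ][1, ]
      rseq <- corrected$reads$seq[corrected$reads$id == id]
      if (a$strand == "-") rseq <- revcomp(rseq)
      L <- nchar(rseq)
      seg <- if (a$strand == "+") substr(rseq, a$read_end + 1, b$read_start)
             else substr(rseq, L - a$read_start + 1, L - b$read_end)
      counts <- c(counts, count_repeat_units(seg, unit_nt, 0.7))
    }
    expect_gte(length(counts), 3)
    tab <- table(counts)
    expect_identical(as.integer(names(tab)[which.max(tab)]), R)
  }
})
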