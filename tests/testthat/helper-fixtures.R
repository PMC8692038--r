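# Shared fixture builders for the test suite. Everything is generated in
# code under explicit seeds; no binary fixtures.

AA <- silkforge:::AA20

random_protein <- function(n, seed = NULL) {
  gen <- function() paste0(sample(AA, n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else silkforge:::with_seed(seed, gen())
}

random_dna_str <- function(n, seed = NULL) {
  gen <- function() paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) gen() else silkforge:::with_seed(seed, gen())
}

# mutate `nmut` residues of a protein (substitutions only)
mutate_protein <- function(seq, nmut) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), nmut)
  for (i in idx) ch[i] <- sample(setdiff(AA, ch[i]), 1)
  paste0(ch, collapse = "")
}

# random binary tree with positive branch lengths; returns ape phylo
random_additive_tree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}

# per-read mismatch count against the recorded origin truth
count_truth_mismatches <- function(rs, source) {
  sum(vapply(seq_len(nrow(rs$reads)), function(i) {
    t <- rs$truth[rs$truth$id == rs$reads$id[i], ]
    tr <- substr(source, t$start + 1, t$end)
    if (t$strand == "-") tr <- revcomp(tr)
    sum(strsplit(rs$reads$seq[i], "")[[1]] != strsplit(tr, "")[[1]])
  }, numeric(1)))
}

# reference MaSp4 study gene and flanked source used across assembly tests
study_gene <- function(seed = 1L) build_gene("MaSp4", 12, 40, seed = seed)

study_source <- function(gene, seed = 102L, flank = 300L) {
  silkforge:::with_seed(seed, paste0(silkforge:::random_dna(flank),
                                     gene$cds_nt,
                                     silkforge:::random_dna(flank)))
}

identity_vs <- function(query, target) {
  f <- silkforge:::alignment_identity(Biostrings::pairwiseAlignment(
    query, target, type = "global-local",
    substitutionMatrix = silkforge:::dna_submat(),
    gapOpening = 5, gapExtension = 2))
  r <- silkforge:::alignment_identity(Biostrings::pairwiseAlignment(
    revcomp(query), target, type = "global-local",
    substitutionMatrix = silkforge:::dna_submat(),
    gapOpening = 5, gapExtension = 2))
  max(f, r)
}

# run the seed-and-extend chain on a read set; returns both candidates
assemble_candidates <- function(short, min_count = "auto",
                                min_score = 150) {
  g <- build_debruijn(short, 31, min_count)
  utg <- extract_unitigs(g)
  seeds <- find_terminal_seeds(utg, terminal_domains(), min_score)
  sn <- seeds[seeds$domain_kind == "N", ][1, ]
  sc <- seeds[seeds$domain_kind == "C", ][1, ]
  list(n = extend_seed(sn, short, name = "N"),
       c = extend_seed(sc, short, direction = "5p", name = "C"))
}
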