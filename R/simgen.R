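#' Read-set container
#'
#' Bundles simulated or parsed sequencing reads with, where available, the
#' ground-truth origin of each read on its source sequence (0-based
#' half-open coordinates, strand as "+"/"-").
#'
#' @param reads data.frame with columns \code{id}, \code{seq}, \code{qual}
#'   (Phred+33 string or \code{NA}), \code{mate} (mate read id or \code{NA}).
#' @param platform "short" or "long".
#' @param truth optional data.frame with columns \code{id}, \code{start},
#'   \code{end}, \code{strand} on the source sequence.
#' @return object of class \code{read_set}.
#' @export
read_set <- function(reads, platform = c("short", "long"), truth = NULL) {
  platform <- match.arg(platform)
  stopifnot(is.data.frame(reads),
            all(c("id", "seq", "qual", "mate") %in% names(reads)))
  has_q <- !is.na(reads$qual)
  if (any(has_q) && !all(nchar(reads$qual[has_q]) == nchar(reads$seq[has_q])))
    stop("quality string length must equal sequence length")
  if (!is.null(truth)) {
    stopifnot(all(c("id", "start", "end", "strand") %in% names(truth)))
    if (any(truth$start < 0) || any(truth$end < truth$start))
      stop("invalid origin intervals in truth table")
  }
  structure(list(reads = reads, platform = platform, truth = truth),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set>", nrow(x$reads), x$platform, "reads,",
      sum(nchar(x$reads$seq)), "bases",
      if (!is.null(x$truth)) "(with origin truth)" else "", "\n")
  invisible(x)
}

#' @export
length.read_set <- function(x) nrow(x$reads)

spacer_alphabet <- c("G", "S", "Q", "P", "Y", "L", "V")
spacer_weights  <- c(0.30, 0.20, 0.10, 0.10, 0.10, 0.10, 0.10)

# one tail string for a family grammar (uses current RNG stream)
sample_tail <- function(grammar) {
  rule <- grammar$tail_rule[1]
  switch(rule,
    poly_A = if (length(grammar$tail_motifs) && runif(1) < 0.4)
               grammar$tail_motifs[sample.int(length(grammar$tail_motifs), 1L)]
             else strrep("A", sample(4:7, 1L)),
    poly_GA = strrep("GA", sample(3:5, 1L)),
    poly_X = grammar$tail_motifs[sample.int(length(grammar$tail_motifs), 1L)],
    none = "",
    stop("unknown tail rule: ", rule))
}

# motifs whose presence would make a unit ambiguous across families
cross_family_motifs <- function(grammar) {
  grams <- spidroin_grammars()
  other <- grams[vapply(grams, function(g)
    g$family != grammar$family && !identical(g$core_motifs, grammar$core_motifs),
    logical(1))]
  setdiff(unique(unlist(lapply(other, `[[`, "core_motifs"))),
          grammar$core_motifs)
}

# expected detect_tail kind for a tail string under a grammar
expected_tail_kind <- function(grammar, tail) {
  if (nchar(tail) == 0L) return("none")
  detect_tail(tail)$kind
}

#' Build a synthetic spidroin gene model
#'
#' Constructs a spidroin gene with the canonical architecture: conserved
#' N-terminal domain, an array of tandem repeat units drawn from a family
#' motif grammar, and a conserved C-terminal domain. Each repeat unit
#' contains at least one grammar core motif and ends with the grammar's tail
#' (poly-A, poly-GA, poly-X or none); spacer residues exclude alanine so no
#' spurious poly-A runs arise, and units are rejection-sampled so that no
#' other family's core motif occurs by chance. The coding sequence is
#' obtained by reverse translation with codons drawn uniformly among
#' synonymous choices.
#'
#' @param grammar a \code{motif_grammar} or family label (see
#'   \code{\link{spidroin_grammars}}).
#' @param n_repeats number of repeat units (may be 0).
#' @param repeat_len_aa length of each unit in amino acids; must accommodate
#'   the longest core motif plus the tail.
#' Spidroin repeat arrays are nearly homogeneous tandem copies at the
#' nucleotide level — the property that collapses them in short-read
#' assemblies. The generator therefore samples one unit per gene and
#' tandem-duplicates its coding sequence; \code{repeat_divergence} > 0
#' instead mutates each copy's amino acids at that rate (re-translated
#' independently) for less idealised arrays.
#'
#' @param seed integer seed; the gene is deterministic for a fixed seed.
#' @param name optional gene name.
#' @param repeat_divergence per-residue substitution rate between repeat
#'   copies (default 0: exact tandem nucleotide copies).
#' @return object of class \code{spidroin_gene} with fields \code{name},
#'   \code{family}, \code{ntd}, \code{repeats} (list of repeat units),
#'   \code{ctd}, \code{cds_nt} and \code{protein}.
#' @export
build_gene <- function(grammar, n_repeats, repeat_len_aa, seed = 1L,
                       name = NULL, repeat_divergence = 0) {
  if (is.character(grammar)) grammar <- spidroin_grammars(grammar)
  stopifnot(inherits(grammar, "motif_grammar"))
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 0L) stop("n_repeats must be nonnegative")
  core_max <- max(nchar(grammar$core_motifs))
  if (repeat_len_aa < core_max)
    stop("repeat_len_aa (", repeat_len_aa, ") shorter than the longest ",
         "grammar motif (", core_max, ")")
  bad <- cross_family_motifs(grammar)
  doms <- terminal_domains()
  ntd <- doms[[paste0(grammar$family, "_NTD")]]
  ctd <- doms[[paste0(grammar$family, "_CTD")]]
  if (is.null(ntd) || is.null(ctd))
    stop("no packaged terminal domains for family ", grammar$family)
  with_seed(seed, {
    sample_unit <- function() {
      for (try in 1:100) {
        tail <- sample_tail(grammar)
        body_len <- repeat_len_aa - nchar(tail)
        if (body_len < core_max)
          stop("repeat_len_aa too small for core motif plus '",
               grammar$tail_rule[1], "' tail")
        core <- grammar$core_motifs[sample.int(length(grammar$core_motifs), 1L)]
        pre_len <- sample(0:min(3L, body_len - nchar(core)), 1L)
        fill_len <- body_len - pre_len - nchar(core)
        spac <- function(n) if (n == 0L) "" else
          paste0(sample(spacer_alphabet, n, TRUE, spacer_weights),
                 collapse = "")
        cand <- paste0(spac(pre_len), core, spac(fill_len), tail)
        ok <- !any(vapply(bad, function(m) grepl(m, cand, fixed = TRUE),
                          logical(1))) &&
          detect_tail(cand)$kind == expected_tail_kind(grammar, tail)
        if (ok) return(cand)
      }
      stop("failed to sample an unambiguous repeat unit for ",
           grammar$family)
    }
    units <- list(); unit_nts <- character(0)
    if (n_repeats > 0L) {
      base_aa <- sample_unit()
      base_nt <- reverse_translate(base_aa)
      for (i in seq_len(n_repeats)) {
        if (repeat_divergence > 0) {
          ch <- strsplit(base_aa, "")[[1]]
          mut <- which(runif(length(ch)) < repeat_divergence)
          for (m in mut) ch[m] <- sample(setdiff(spacer_alphabet, ch[m]), 1L)
          aa_i <- paste0(ch, collapse = "")
          nt_i <- reverse_translate(aa_i)
        } else {
          aa_i <- base_aa
          nt_i <- base_nt
        }
        units[[i]] <- scan_motifs(aa_i, grammar)
        unit_nts[i] <- nt_i
      }
    }
    rep_aa <- paste0(vapply(units, `[[`, "", "aa_seq"), collapse = "")
    protein <- paste0(ntd, rep_aa, ctd)
    cds <- paste0(reverse_translate(ntd), paste0(unit_nts, collapse = ""),
                  reverse_translate(ctd))
    structure(list(
      name = if (is.null(name)) paste0(grammar$family, "_syn") else name,
      family = grammar$family, ntd = ntd, repeats = units, ctd = ctd,
      cds_nt = cds, protein = protein), class = "spidroin_gene")
  })
}

#' @export
print.spidroin_gene <- function(x, ...) {
  cat("<spidroin_gene>", x$name, "family", x$family, "\n")
  cat("  NTD", nchar(x$ntd), "aa |", length(x$repeats), "repeat units",
      if (length(x$repeats)) paste0("x ", nchar(x$repeats[[1]]$aa_seq), " aa"),
      "| CTD", nchar(x$ctd), "aa; CDS", nchar(x$cds_nt), "nt\n")
  invisible(x)
}

apply_substitutions <- function(seq, err_rate) {
  if (err_rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < err_rate)
  for (i in hit) {
    alt <- setdiff(DNA_BASES4, ch[i])
    ch[i] <- alt[sample.int(3L, 1L)]
  }
  paste0(ch, collapse = "")
}

phred_char <- function(err_rate) {
  q <- if (err_rate <= 0) 40L else min(40L, max(2L, round(-10 * log10(err_rate))))
  intToUtf8(q + 33L)
}

#' Simulate Illumina-like short reads
#'
#' Uniformly placed fixed-length reads from both strands of a source
#' sequence, with i.i.d. substitution errors. The read count equals
#' \code{round(coverage * len(source) / read_len)} (in paired mode the count
#' is rounded to the nearest even number; mates count as two reads). Origin
#' coordinates (0-based half-open, pre-error) are recorded for every read.
#' Quality strings are a constant Phred+33 value matching the error rate.
#'
#' @param source nucleotide sequence (character scalar).
#' @param coverage target fold coverage.
#' @param read_len read length; must not exceed the source length.
#' @param err_rate per-base substitution probability.
#' @param paired simulate read pairs from normal-insert fragments.
#' @param insert_mean mean fragment length for paired mode; the insert-size
#'   standard deviation is 10\% of the mean.
#' @param seed integer seed (deterministic for a fixed seed).
#' @return a \code{\link{read_set}} with platform "short".
#' @export
simulate_short_reads <- function(source, coverage, read_len, err_rate = 0,
                                 paired = FALSE, insert_mean = 500L,
                                 seed = 1L) {
  L <- nchar(source)
  if (read_len > L) stop("read_len (", read_len, ") exceeds source length (",
                         L, ")")
  n <- round(coverage * L / read_len)
  with_seed(seed, {
    qc <- phred_char(err_rate)
    if (!paired) {
      starts <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
      strands <- sample(c("+", "-"), n, replace = TRUE)
      raw <- substring(source, starts + 1L, starts + read_len)
      seqs <- ifelse(strands == "-", revcomp(raw), raw)
      if (err_rate > 0)
        seqs <- vapply(seqs, apply_substitutions, "", err_rate,
                       USE.NAMES = FALSE)
      ids <- sprintf("sr%05d", seq_len(n))
      reads <- data.frame(id = ids, seq = seqs,
                          qual = strrep(qc, read_len), mate = NA_character_,
                          stringsAsFactors = FALSE)
      truth <- data.frame(id = ids, start = starts, end = starts + read_len,
                          strand = strands, stringsAsFactors = FALSE)
    } else {
      npair <- round(n / 2)
      ins <- pmax(read_len, pmin(L, round(rnorm(npair, insert_mean,
                                                0.1 * insert_mean))))
      fstart <- vapply(ins, function(s) sample.int(L - s + 1L, 1L) - 1L,
                       integer(1))
      fstr <- sample(c("+", "-"), npair, replace = TRUE)
      # R1 from the fragment 5' end on the fragment strand, R2 from the other
      s1 <- ifelse(fstr == "+", fstart, fstart + ins - read_len)
      s2 <- ifelse(fstr == "+", fstart + ins - read_len, fstart)
      str1 <- fstr
      str2 <- ifelse(fstr == "+", "-", "+")
      grab <- function(st, sd) {
        raw <- substring(source, st + 1L, st + read_len)
        ifelse(sd == "-", revcomp(raw), raw)
      }
      seq1 <- grab(s1, str1); seq2 <- grab(s2, str2)
      if (err_rate > 0) {
        seq1 <- vapply(seq1, apply_substitutions, "", err_rate,
                       USE.NAMES = FALSE)
        seq2 <- vapply(seq2, apply_substitutions, "", err_rate,
                       USE.NAMES = FALSE)
      }
      id1 <- sprintf("sr%05d/1", seq_len(npair))
      id2 <- sprintf("sr%05d/2", seq_len(npair))
      reads <- data.frame(id = c(id1, id2), seq = c(seq1, seq2),
                          qual = strrep(qc, read_len),
                          mate = c(id2, id1), stringsAsFactors = FALSE)
      truth <- data.frame(id = c(id1, id2), start = c(s1, s2),
                          end = c(s1, s2) + read_len,
                          strand = c(str1, str2), stringsAsFactors = FALSE)
    }
    read_set(reads, "short", truth)
  })
}

#' Simulate Nanopore-like long reads
#'
#' Read lengths are drawn from a gamma distribution (shape 2, mean
#' \code{mean_len}), truncated to the source length; reads are drawn until
#' the total base count reaches \code{coverage * len(source)}. Errors are
#' split 60\% substitutions, 20\% insertions and 20\% deletions of
#' \code{err_rate}. Origin coordinates refer to the pre-error interval.
#'
#' @inheritParams simulate_short_reads
#' @param mean_len mean read length (>= 500).
#' @return a \code{\link{read_set}} with platform "long".
#' @export
simulate_long_reads <- function(source, coverage, mean_len, err_rate = 0,
                                seed = 1L) {
  if (mean_len < 500) stop("mean_len must be >= 500")
  L <- nchar(source)
  target <- coverage * L
  with_seed(seed, {
    lens <- integer(0)
    while (sum(lens) < target) {
      draw <- pmin(L, pmax(200L, round(rgamma(64L, shape = 2,
                                              scale = mean_len / 2))))
      lens <- c(lens, draw)
    }
    lens <- lens[seq_len(which(cumsum(lens) >= target)[1])]
    n <- length(lens)
    starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L,
                     integer(1))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    qc <- phred_char(err_rate)
    seqs <- character(n)
    for (i in seq_len(n)) {
      raw <- substr(source, starts[i] + 1L, starts[i] + lens[i])
      if (strands[i] == "-") raw <- revcomp(raw)
      if (err_rate > 0) {
        ch <- strsplit(raw, "")[[1]]
        ev <- sample(c("m", "s", "i", "d"), length(ch), replace = TRUE,
                     prob = c(1 - err_rate, 0.6 * err_rate,
                              0.2 * err_rate, 0.2 * err_rate))
        out <- ch
        sub_i <- which(ev == "s")
        for (j in sub_i) out[j] <- setdiff(DNA_BASES4, ch[j])[sample.int(3L, 1L)]
        ins_i <- which(ev == "i")
        for (j in ins_i) out[j] <- paste0(out[j],
                                          DNA_BASES4[sample.int(4L, 1L)])
        out[ev == "d"] <- ""
        raw <- paste0(out, collapse = "")
      }
      seqs[i] <- raw
    }
    ids <- sprintf("lr%04d", seq_len(n))
    reads <- data.frame(id = ids, seq = seqs,
                        qual = vapply(seqs, function(s) strrep(qc, nchar(s)),
                                      "", USE.NAMES = FALSE),
                        mate = NA_character_, stringsAsFactors = FALSE)
    truth <- data.frame(id = ids, start = starts, end = starts + lens,
                        strand = strands, stringsAsFactors = FALSE)
    read_set(reads, "long", truth)
  })
}
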