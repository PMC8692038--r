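#' Correct long reads against a trusted short-read k-mer spectrum
#'
#' A deliberately minimal substitution-repair stage: the trusted spectrum is
#' the set of canonical k-mers occurring at least \code{min_count} times in
#' the short reads. Scanning each long read left to right, a base covered by
#' at least one untrusted k-mer is replaced by the single substitution that
#' makes every covering k-mer trusted — when exactly one such base exists;
#' with zero or several valid repairs the base is left unchanged. Insertions
#' and deletions are not repaired. The output read count equals the input.
#'
#' @param long long-read \code{\link{read_set}}.
#' @param short short-read \code{\link{read_set}} or character vector.
#' @param k spectrum k-mer size (default 15).
#' @param min_count minimum short-read count for a k-mer to be trusted.
#' @return corrected \code{read_set} (ids, truth and platform preserved).
#' @export
correct_long_reads <- function(long, short, k = 15L, min_count = 2L) {
  stopifnot(inherits(long, "read_set"))
  if (inherits(short, "read_set")) short <- short$reads$seq
  km <- unlist(lapply(short, seq_kmers, k = k), use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  cnt <- table(canonical_kmers(km))
  good <- names(cnt)[as.integer(cnt) >= min_count]
  trusted <- new.env(hash = TRUE, parent = emptyenv())
  # store both orientations so lookups skip canonicalization
  for (x in c(good, revcomp(good))) trusted[[x]] <- TRUE
  is_trusted <- function(kmer) !is.null(trusted[[kmer]])
  fix_read <- function(seq) {
    n <- nchar(seq)
    if (n < k) return(seq)
    ch <- strsplit(seq, "")[[1]]
    kms <- seq_kmers(seq, k)
    flag <- vapply(kms, is_trusted, logical(1), USE.NAMES = FALSE)
    if (all(flag)) return(seq)
    for (i in seq_len(n)) {
      jr <- max(1L, i - k + 1L):min(i, n - k + 1L)
      if (all(flag[jr])) next
      fixes <- character(0)
      for (b in setdiff(DNA_BASES4, ch[i])) {
        ok <- TRUE
        for (j in jr) {
          kmer <- paste0(ch[j:(j + k - 1L)], collapse = "")
          substr(kmer, i - j + 1L, i - j + 1L) <- b
          if (!is_trusted(kmer)) { ok <- FALSE; break }
        }
        if (ok) fixes <- c(fixes, b)
      }
      if (length(fixes) == 1L) {
        ch[i] <- fixes
        for (j in jr)
          flag[j] <- is_trusted(paste0(ch[j:(j + k - 1L)], collapse = ""))
      }
    }
    paste0(ch, collapse = "")
  }
  out <- long
  out$reads$seq <- vapply(long$reads$seq, fix_read, "", USE.NAMES = FALSE)
  # substitution repair preserves read length, so qualities are kept
  out
}

#' Map an assembly candidate onto long reads
#'
#' Shared \code{seed_k}-mers between the candidate and each read (each
#' strand) are collected and filtered to a colinear chain by diagonal
#' consistency; the chained region is then bridged with a single banded-style
#' alignment of the whole candidate against the spanned read window
#' (global-local), and supports with identity >= \code{min_identity} are
#' returned. Coordinates are reported on the forward strand of the read.
#' Identity is computed over aligned columns.
#'
#' @param candidate an \code{assembly_candidate} or nucleotide string.
#' @param long long-read \code{\link{read_set}}.
#' @param seed_k anchor k-mer length for mapping (default 15).
#' @param min_identity minimum alignment identity (default 0.8).
#' @param name candidate name used in the support table.
#' @return data.frame of class \code{long_read_support}: \code{read_id},
#'   \code{candidate_name}, \code{read_start}, \code{read_end} (0-based
#'   half-open, forward strand), \code{strand}, \code{identity},
#'   \code{full_length} (NA here; see \code{\link{flag_full_length}}).
#' @export
map_candidate <- function(candidate, long, seed_k = 15L, min_identity = 0.8,
                          name = NULL) {
  cand <- if (inherits(candidate, "assembly_candidate"))
    candidate$consensus else candidate
  if (is.null(name))
    name <- if (inherits(candidate, "assembly_candidate"))
      candidate$name else "candidate"
  stopifnot(inherits(long, "read_set"))
  if (nchar(cand) < seed_k)
    stop("candidate shorter than seed_k (", seed_k, ")")
  ckm <- seq_kmers(cand, seed_k)
  cpos <- new.env(hash = TRUE, parent = emptyenv())
  for (i in rev(seq_along(ckm))) cpos[[ckm[i]]] <- i   # first occurrence wins
  rows <- list()
  for (ri in seq_len(nrow(long$reads))) {
    rseq0 <- long$reads$seq[ri]
    L <- nchar(rseq0)
    best <- NULL
    for (strand in c("+", "-")) {
      rseq <- if (strand == "+") rseq0 else revcomp(rseq0)
      rkm <- seq_kmers(rseq, seed_k)
      hit <- which(vapply(rkm, function(x) !is.null(cpos[[x]]), logical(1),
                          USE.NAMES = FALSE))
      if (length(hit) < 2L) next
      cp <- vapply(rkm[hit], function(x) cpos[[x]], integer(1),
                   USE.NAMES = FALSE)
      diag <- hit - cp
      med <- median(diag)
      band <- max(50, 0.2 * nchar(cand))
      keep <- abs(diag - med) <= band
      if (sum(keep) < 2L) next
      med <- median(diag[keep])
      pad <- round(0.1 * nchar(cand)) + 20L
      wstart <- max(1L, round(med + 1L - pad))
      wend <- min(L, round(med + nchar(cand) + pad))
      if (wend - wstart + 1L < seed_k) next
      wseq <- substr(rseq, wstart, wend)
      aln <- Biostrings::pairwiseAlignment(
        cand, wseq, type = "global-local",
        substitutionMatrix = dna_submat(), gapOpening = 5, gapExtension = 2)
      idy <- alignment_identity(aln)
      sr <- aln@subject@range
      a <- wstart + sr@start - 1L          # 1-based on oriented read
      b <- a + sr@width - 1L
      if (strand == "+") {
        fs <- a - 1L; fe <- b
      } else {
        fs <- L - b; fe <- L - a + 1L
      }
      cand_row <- list(strand = strand, identity = idy,
                       read_start = fs, read_end = fe)
      if (is.null(best) || idy > best$identity) best <- cand_row
    }
    if (!is.null(best) && best$identity >= min_identity)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = long$reads$id[ri], candidate_name = name,
        read_start = best$read_start, read_end = best$read_end,
        strand = best$strand, identity = best$identity,
        full_length = NA, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), candidate_name = character(0),
               read_start = integer(0), read_end = integer(0),
               strand = character(0), identity = numeric(0),
               full_length = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("long_read_support", class(out))
  out
}

#' Flag full-length long-read supports
#'
#' A read supports the full-length architecture when the N-side and C-side
#' candidates of the same gene both map to it on the same strand, in gene
#' order (N before C on the gene-forward orientation of the read).
#'
#' @param sup_n,sup_c support tables from \code{\link{map_candidate}} for
#'   the N-side and C-side candidates.
#' @return combined support table with \code{full_length} set.
#' @export
flag_full_length <- function(sup_n, sup_c) {
  out <- rbind(as.data.frame(sup_n), as.data.frame(sup_c))
  out$full_length <- FALSE
  shared <- intersect(sup_n$read_id, sup_c$read_id)
  for (id in shared) {
    a <- sup_n[sup_n$read_id == id, ][1, ]
    b <- sup_c[sup_c$read_id == id, ][1, ]
    if (a$strand != b$strand) next
    ok <- if (a$strand == "+") a$read_start < b$read_start
          else a$read_start > b$read_start
    if (ok) out$full_length[out$read_id == id] <- TRUE
  }
  class(out) <- c("long_read_support", "data.frame")
  out
}

#' Count tandem repeat units in a read segment
#'
#' Greedy left-to-right non-overlapping tiling of the segment by alignments
#' of a repeat-unit sequence: at each cursor position the unit is aligned
#' (global on the unit, local on a 1.5-unit window); a tile is accepted when
#' its identity reaches \code{min_identity}, advancing the cursor past the
#' tile; otherwise the cursor advances by one unit length. Ties between
#' overlapping tilings are resolved by earliest start.
#'
#' @param read_segment nucleotide sequence.
#' @param unit repeat-unit nucleotide sequence (>= 20 nt).
#' @param min_identity minimum tile identity (default 0.75).
#' @return integer tile count.
#' @export
count_repeat_units <- function(read_segment, unit, min_identity = 0.75) {
  ulen <- nchar(unit)
  if (ulen < 20L) stop("unit must be at least 20 nt")
  n <- nchar(read_segment)
  count <- 0L
  p <- 1L
  while (p <= n - floor(0.6 * ulen)) {
    wend <- min(n, p + round(1.5 * ulen))
    w <- substr(read_segment, p, wend)
    aln <- Biostrings::pairwiseAlignment(
      unit, w, type = "global-local",
      substitutionMatrix = dna_submat(), gapOpening = 5, gapExtension = 2)
    idy <- alignment_identity(aln)
    # a tile must also cover most of one unit: short gappy alignments can
    # reach high per-column identity without representing a repeat copy
    tile_w <- aln@subject@range@width
    if (idy >= min_identity && tile_w >= 0.75 * ulen) {
      count <- count + 1L
      sr <- aln@subject@range
      p <- p + sr@start + sr@width - 1L
    } else {
      p <- p + ulen
    }
  }
  count
}
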