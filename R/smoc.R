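#' Find terminal-domain seeds on assembled contigs
#'
#' Six-frame translates each contig and locally aligns every frame against a
#' set of reference terminal-domain proteins (affine gaps, BLOSUM62, gap
#' open 10 / extend 1). Hits with score >= \code{min_score} are returned as
#' seeds with nucleotide coordinates reported on the forward strand of the
#' contig, sorted by score descending. Domain kind (N or C) is taken from
#' the reference name suffix \code{_NTD} / \code{_CTD}. Contigs shorter
#' than 3 nt are skipped with a warning.
#'
#' @param contigs named character vector of contig sequences (see
#'   \code{\link{extract_unitigs}}).
#' @param domains named character vector of terminal-domain amino-acid
#'   sequences (see \code{\link{terminal_domains}}).
#' @param min_score minimum local alignment score.
#' @return data.frame of seeds: \code{contig_id}, \code{contig_seq},
#'   \code{hit_start}, \code{hit_end} (0-based half-open nt, forward
#'   strand), \code{strand}, \code{frame}, \code{domain_kind},
#'   \code{domain_name}, \code{score}.
#' @export
find_terminal_seeds <- function(contigs, domains, min_score = 150) {
  if (length(domains) == 0L) stop("domains must be nonempty")
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("utg%05d", seq_along(contigs))
  dom_set <- Biostrings::AAStringSet(domains)
  max_resid <- max(blosum62())     # best attainable per-column score
  rows <- list()
  for (ci in seq_along(contigs)) {
    ctg <- contigs[[ci]]
    n <- nchar(ctg)
    if (n < 3L) {
      warning("contig ", names(contigs)[ci], " shorter than 3 nt; skipped")
      next
    }
    # a contig of n nt cannot score above max_resid * floor(n/3)
    if (max_resid * (n %/% 3L) < min_score) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") ctg else revcomp(ctg)
      for (frame in 0:2) {
        aalen <- (n - frame) %/% 3L
        if (aalen < 5L) next
        aa <- translate_nt(substr(s, frame + 1L, frame + 3L * aalen))
        aa <- gsub("*", "X", aa, fixed = TRUE)
        alns <- Biostrings::pairwiseAlignment(
          dom_set, aa, type = "local", substitutionMatrix = blosum62(),
          gapOpening = 10, gapExtension = 1)
        scs <- Biostrings::score(alns)
        for (di in which(scs >= min_score)) {
          sr <- alns[di]@subject@range
          aa_start <- sr@start
          aa_end <- sr@start + sr@width - 1L
          nt_start <- frame + 3L * (aa_start - 1L)       # 0-based on s
          nt_end <- frame + 3L * aa_end                  # half-open
          if (strand == "+") {
            fs <- nt_start; fe <- nt_end
          } else {
            fs <- n - nt_end; fe <- n - nt_start
          }
          dn <- names(domains)[di]
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = names(contigs)[ci], contig_seq = ctg,
            hit_start = fs, hit_end = fe, strand = strand, frame = frame,
            domain_kind = if (grepl("_NTD$", dn)) "N" else
              if (grepl("_CTD$", dn)) "C" else NA_character_,
            domain_name = dn, score = scs[di], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(0), contig_seq = character(0),
                      hit_start = integer(0), hit_end = integer(0),
                      strand = character(0), frame = integer(0),
                      domain_kind = character(0), domain_name = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the onset of tandem periodicity in a nucleotide sequence
#'
#' Slides a window over the sequence and tests, for each candidate period
#' q up to \code{period_max}, the fraction of window positions i with
#' base(i) == base(i + q) (the lagged self-match, an autocorrelation on the
#' base sequence). Returns the smallest 0-based position p at which some
#' period achieves a self-match fraction >= 0.9 over the window starting at
#' p, i.e. the estimated boundary where a repeat array begins. The detected
#' period is attached as attribute \code{"period"}. NULL when no window is
#' periodic.
#'
#' @param consensus nucleotide sequence.
#' @param window window length; must be at least \code{2 * period_max}.
#' @param period_max largest candidate period (nt).
#' @param min_frac self-match fraction required (default 0.9).
#' @return integer position (0-based) with attribute \code{period}, or NULL.
#' @export
detect_repeat_boundary <- function(consensus, window = 300L,
                                   period_max = 150L, min_frac = 0.9) {
  if (window < 2L * period_max)
    stop("window must be at least 2 * period_max")
  n <- nchar(consensus)
  if (n < window) return(NULL)
  s <- utf8ToInt(consensus)
  npos <- n - window + 1L               # candidate starts (1-based)
  best_frac <- rep(0, npos)
  best_q <- rep(NA_integer_, npos)
  for (q in 1:period_max) {
    m <- s[1:(n - q)] == s[(1L + q):n]
    cm <- c(0, cumsum(m))
    wlen <- window - q                  # comparisons inside the window
    # window starting at p (1-based) covers comparisons p .. p+wlen-1
    f <- (cm[(wlen + 1L):(wlen + npos)] - cm[1:npos]) / wlen
    upd <- f > best_frac
    best_frac[upd] <- f[upd]
    best_q[upd] <- q
  }
  hit <- which(best_frac >= min_frac)
  if (!length(hit)) return(NULL)
  p <- hit[1]
  structure(p - 1L, period = best_q[p])
}

# is the trailing window of `consensus` periodic? (cheap check used during
# extension; same test as detect_repeat_boundary at the last position)
trailing_periodic <- function(consensus, window, period_max, min_frac = 0.9) {
  n <- nchar(consensus)
  if (n < window) return(FALSE)
  s <- utf8ToInt(substr(consensus, n - window + 1L, n))
  for (q in 1:period_max) {
    if (mean(s[1:(window - q)] == s[(1L + q):window]) >= min_frac)
      return(TRUE)
  }
  FALSE
}

#' Extend a terminal-domain seed through a position weight matrix
#'
#' The SMoC extension step: starting from the seed contig, the terminal
#' anchor k-mer of the current consensus is matched exactly against the
#' short reads (both orientations); the bases each matching read contributes
#' beyond the anchor are stacked into position-weight-matrix columns, and a
#' column's majority base is appended while its depth is at least
#' \code{min_depth} and its majority frequency at least \code{min_frac}
#' (ties halt rather than guess). The loop re-anchors after each batch and
#' halts with reason \code{repeat_boundary} when the trailing window becomes
#' tandem-periodic (\code{\link{detect_repeat_boundary}}),
#' \code{no_support} when no column passes, or \code{max_length} at the
#' length cap.
#'
#' @param seed one seed row from \code{\link{find_terminal_seeds}} (or a
#'   list with \code{contig_seq}, \code{strand}, and optionally
#'   \code{hit_start}, \code{hit_end}, \code{domain_name}).
#' @param reads short-read \code{\link{read_set}} or character vector.
#' @param anchor_k extension anchor k-mer length ("extremely large" k;
#'   default 51). Must be below the read length.
#' @param min_depth,min_frac stringent PWM thresholds (defaults 5 and 0.8).
#' @param max_len consensus length cap.
#' @param direction "3p" extends the gene-forward seed rightward (N-side);
#'   "5p" extends leftward by working on the reverse complement (C-side).
#'   The consensus is always reported in the growth orientation (the
#'   extended end is its 3' end).
#' @param window,period_max repeat-boundary detection parameters.
#' @param name candidate name.
#' @return object of class \code{assembly_candidate}: \code{name},
#'   \code{consensus}, \code{seed}, \code{support} (data.frame
#'   \code{pos} (0-based), \code{depth}, \code{max_frac}; seed-derived
#'   prefix positions are absent), \code{boundary_pos} (0-based, or NA),
#'   \code{halted_reason}, \code{direction}, \code{seed_len} (length of the
#'   seed-derived prefix).
#' @export
extend_seed <- function(seed, reads, anchor_k = 51L, min_depth = 5L,
                        min_frac = 0.8, max_len = 20000L,
                        direction = c("3p", "5p"), window = 300L,
                        period_max = 150L, name = "candidate") {
  direction <- match.arg(direction)
  if (min_frac <= 0.5 || min_frac > 1)
    stop("min_frac must be in (0.5, 1]")
  if (inherits(reads, "read_set")) reads <- reads$reads$seq
  if (anchor_k > min(nchar(reads)) - 1L)
    stop("anchor_k must be below the read length")
  ctg <- seed$contig_seq
  oriented <- if (identical(seed$strand, "-")) revcomp(ctg) else ctg
  working <- if (direction == "5p") revcomp(oriented) else oriented
  pool_f <- reads
  pool_r <- revcomp(reads)
  consensus <- working
  seed_len <- nchar(consensus)
  sup_pos <- integer(0); sup_depth <- integer(0); sup_frac <- numeric(0)
  halted <- NULL
  repeat {
    n <- nchar(consensus)
    if (n >= max_len) { halted <- "max_length"; break }
    anchor <- substr(consensus, n - anchor_k + 1L, n)
    if (grepl("N", anchor, fixed = TRUE)) { halted <- "no_support"; break }
    hits_f <- regexpr(anchor, pool_f, fixed = TRUE)
    hits_r <- regexpr(anchor, pool_r, fixed = TRUE)
    over <- c(substring(pool_f[hits_f > 0], hits_f[hits_f > 0] + anchor_k),
              substring(pool_r[hits_r > 0], hits_r[hits_r > 0] + anchor_k))
    over <- over[nzchar(over)]
    appended <- 0L
    if (length(over)) {
      maxw <- max(nchar(over))
      for (j in seq_len(maxw)) {
        bases <- substr(over, j, j)
        bases <- bases[bases %in% DNA_BASES4]
        depth <- length(bases)
        if (depth < min_depth) break
        tab <- tabulate(match(bases, DNA_BASES4), 4L)
        top <- max(tab)
        if (sum(tab == top) > 1L) break          # tie: do not guess
        frac <- top / depth
        if (frac < min_frac) break
        consensus <- paste0(consensus, DNA_BASES4[which.max(tab)])
        sup_pos <- c(sup_pos, nchar(consensus) - 1L)
        sup_depth <- c(sup_depth, depth)
        sup_frac <- c(sup_frac, frac)
        appended <- appended + 1L
        if (nchar(consensus) >= max_len) break
      }
    }
    if (appended == 0L) { halted <- "no_support"; break }
    if (trailing_periodic(consensus, window, period_max)) {
      halted <- "repeat_boundary"; break
    }
  }
  # boundary reported whenever the consensus shows periodicity, even if the
  # walk halted for another reason (e.g. the PWM split at the far junction
  # of a short collapsed array)
  boundary <- NA_integer_; period <- NA_integer_
  b <- detect_repeat_boundary(consensus, window, period_max)
  if (!is.null(b)) { boundary <- as.integer(b); period <- attr(b, "period") }
  structure(list(name = name, consensus = consensus, seed = seed,
                 support = data.frame(pos = sup_pos, depth = sup_depth,
                                      max_frac = sup_frac),
                 boundary_pos = boundary, boundary_period = period,
                 halted_reason = halted, direction = direction,
                 seed_len = seed_len),
            class = "assembly_candidate")
}

#' @export
print.assembly_candidate <- function(x, ...) {
  cat("<assembly_candidate>", x$name, nchar(x$consensus), "nt (seed",
      x$seed_len, "nt), halted:", x$halted_reason,
      if (!is.na(x$boundary_pos))
        paste0("boundary at ", x$boundary_pos,
               " (period ", x$boundary_period, ")"), "\n")
  invisible(x)
}
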