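#' Classify the tail of a repeat unit
#'
#' The tail is the suffix block that ends a spidroin repeat unit. Rules, in
#' order of precedence: a trailing run of >= 4 'A' is a poly-A tail; a
#' trailing tandem of >= 3 "GA" is a poly-GA tail; a trailing stretch of
#' >= 6 residues drawn from the neutral set \{S, V, I, T, L\} is a poly-X
#' tail; otherwise the unit has no tail.
#'
#' @param aa amino-acid string.
#' @return list with \code{kind} ("poly_A", "poly_GA", "poly_X" or "none")
#'   and \code{seq} (the tail suffix, possibly "").
#' @export
detect_tail <- function(aa) {
  m <- regmatches(aa, regexpr("A{4,}$", aa))
  if (length(m) == 1L) return(list(kind = "poly_A", seq = m))
  m <- regmatches(aa, regexpr("(GA){3,}$", aa))
  if (length(m) == 1L) return(list(kind = "poly_GA", seq = m))
  m <- regmatches(aa, regexpr("[SVITL]{6,}$", aa))
  if (length(m) == 1L) return(list(kind = "poly_X", seq = m))
  list(kind = "none", seq = "")
}

new_repeat_unit <- function(aa_seq, motif_hits, tail_kind, tail_seq) {
  structure(list(aa_seq = aa_seq, motif_hits = motif_hits,
                 tail_kind = tail_kind, tail_seq = tail_seq),
            class = "repeat_unit")
}

#' @export
print.repeat_unit <- function(x, ...) {
  cat("<repeat_unit>", nchar(x$aa_seq), "aa, tail", x$tail_kind,
      if (nrow(x$motif_hits)) paste0("(", nrow(x$motif_hits), " motif hits)"),
      "\n  ", x$aa_seq, "\n")
  invisible(x)
}

#' Scan a repeat unit against a family motif grammar
#'
#' Records exact-substring hits of all core and tail motifs (start offsets
#' are 0-based) and classifies the unit tail via \code{\link{detect_tail}}.
#'
#' @param unit amino-acid string or \code{repeat_unit}.
#' @param grammar a \code{motif_grammar}.
#' @return annotated \code{repeat_unit}.
#' @export
scan_motifs <- function(unit, grammar) {
  aa <- if (inherits(unit, "repeat_unit")) unit$aa_seq else unit
  motifs <- c(setNames(grammar$core_motifs,
                       rep("core", length(grammar$core_motifs))),
              setNames(grammar$tail_motifs,
                       rep("tail", length(grammar$tail_motifs))))
  hits <- list()
  for (i in seq_along(motifs)) {
    p <- gregexpr(motifs[[i]], aa, fixed = TRUE)[[1]]
    if (p[1] != -1L)
      hits[[length(hits) + 1L]] <-
        data.frame(motif = motifs[[i]], start = as.integer(p) - 1L,
                   kind = names(motifs)[i], stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif = character(0), start = integer(0),
               kind = character(0), stringsAsFactors = FALSE)
  tl <- detect_tail(aa)
  new_repeat_unit(aa, hits, tl$kind, tl$seq)
}

# does a unit's tail satisfy one tail rule of a grammar?
tail_agrees <- function(unit, rule, grammar) {
  if (rule == "none") return(unit$tail_kind == "none" &&
                             !tail_motif_suffix(unit, grammar))
  if (unit$tail_kind == rule) return(TRUE)
  # explicit tail motifs (e.g. SSSVAISL for MaSp1 poly-A mixing) also count
  tail_motif_suffix(unit, grammar)
}

tail_motif_suffix <- function(unit, grammar) {
  any(vapply(grammar$tail_motifs, function(m) endsWith(unit$aa_seq, m),
             logical(1)))
}

#' Classify a spidroin family from its repeat units
#'
#' Scores each packaged family grammar as the fraction of units containing
#' at least one core motif, plus a tail-agreement bonus (0.5 per unit for
#' the grammar's primary tail rule, 0.25 for a secondary rule, averaged over
#' units). The winner is the highest score with a deterministic tie-break by
#' the fixed grammar order. Nomenclature favours repeat content: when an
#' N-terminal-domain clade assignment is supplied and disagrees with the
#' motif winner's clade, the motif winner is still returned, with
#' \code{conflict = TRUE}. An NTD assignment in the winner's own clade (e.g.
#' a MaSp2-clade NTD for a MaSp4 repeat grammar) is not a conflict.
#'
#' @param units list of \code{repeat_unit} or amino-acid strings.
#' @param ntd_assignment optional family or clade label from NTD homology.
#' @param grammars list of grammars, default \code{\link{spidroin_grammars}()}.
#' @return list with \code{family}, \code{scores} (named vector),
#'   \code{conflict} and \code{ntd_assignment}.
#' @export
classify_family <- function(units, ntd_assignment = NULL,
                            grammars = spidroin_grammars()) {
  if (length(units) == 0L)
    return(list(family = "other",
                scores = setNames(numeric(length(grammars)), names(grammars)),
                conflict = FALSE, ntd_assignment = ntd_assignment))
  scores <- setNames(numeric(length(grammars)), names(grammars))
  for (gi in seq_along(grammars)) {
    g <- grammars[[gi]]
    su <- lapply(units, scan_motifs, grammar = g)
    core_frac <- mean(vapply(su, function(u)
      any(u$motif_hits$kind == "core"), logical(1)))
    bonus <- mean(vapply(su, function(u) {
      if (tail_agrees(u, g$tail_rule[1], g)) return(0.5)
      for (r in g$tail_rule[-1]) if (tail_agrees(u, r, g)) return(0.25)
      0
    }, numeric(1)))
    scores[gi] <- core_frac + bonus
  }
  win <- names(scores)[which.max(scores)]
  conflict <- FALSE
  if (!is.null(ntd_assignment)) {
    ntd_clade <- family_clade(ntd_assignment)
    win_clade <- family_clade(win)
    conflict <- !is.na(ntd_clade) && !is.na(win_clade) &&
      ntd_clade != win_clade
  }
  list(family = win, scores = scores, conflict = conflict,
       ntd_assignment = ntd_assignment)
}

#' Decompose a repetitive protein into tandem repeat units
#'
#' Estimates the dominant repeat period by maximising, over candidate lags,
#' the number of self-matching positions within the best contiguous
#' repetitive span (sliding windows of one period with >= 80\% identity at
#' that lag), then segments that span into consecutive units of the period
#' length, trimming non-repetitive flanks. Ties between equally scoring
#' lags are broken toward the shortest period.
#'
#' @param protein amino-acid sequence; must be at least \code{2 * period_min}
#'   long.
#' @param period_min,period_max candidate period bounds (aa).
#' @return list of \code{repeat_unit} (unannotated; see
#'   \code{\link{scan_motifs}}), empty for non-repetitive input.
#' @export
decompose_repeats <- function(protein, period_min = 5L, period_max = 200L) {
  n <- nchar(protein)
  if (n < 2L * period_min)
    stop("protein shorter than 2 * period_min")
  s <- strsplit(protein, "")[[1]]
  best <- NULL
  for (q in period_min:min(period_max, n - 1L)) {
    m <- s[1:(n - q)] == s[(1L + q):n]
    w <- q
    nm <- length(m)
    if (nm < w) next
    cm <- c(0, cumsum(m))
    roll <- (cm[(w + 1L):(nm + 1L)] - cm[1:(nm - w + 1L)]) / w
    good <- roll >= 0.8
    if (!any(good)) next
    r <- rle(good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    sc_best <- 0L; span_best <- NULL
    for (ri in runs) {
      a <- starts[ri]; b <- ends[ri] + w - 1L   # comparison index range
      # trim flanks to the first/last matching comparison
      while (a <= b && !m[a]) a <- a + 1L
      while (b >= a && !m[b]) b <- b - 1L
      if (a > b) next
      sc <- cm[b + 1L] - cm[a]
      if (sc > sc_best) { sc_best <- sc; span_best <- c(a, b) }
    }
    if (is.null(span_best)) next
    if (is.null(best) || sc_best > best$score) {
      best <- list(q = q, score = sc_best, a = span_best[1],
                   b = span_best[2])
    }
  }
  if (is.null(best)) return(list())
  q <- best$q
  span_start <- best$a                  # 1-based first repetitive residue
  span_end <- best$b + q                # last residue involved in matches
  n_units <- (span_end - span_start + 1L) %/% q
  if (n_units < 2L) return(list())
  lapply(seq_len(n_units), function(j) {
    aa <- substr(protein, span_start + (j - 1L) * q,
                 span_start + j * q - 1L)
    tl <- detect_tail(aa)
    new_repeat_unit(aa, data.frame(motif = character(0), start = integer(0),
                                   kind = character(0),
                                   stringsAsFactors = FALSE),
                    tl$kind, tl$seq)
  })
}

#' Amino-acid composition and cysteine-rich-protein flag
#'
#' Exact residue fractions of a protein, with the cysteine-content flag used
#' to recognise CRP-type silk proteins (SpiCE proteins with high cysteine
#' content, the packaged positive control being a 10\% cysteine case).
#'
#' @param protein amino-acid sequence over the 20-residue alphabet.
#' @param crp_threshold cysteine fraction at or above which \code{is_crp}
#'   is set (default 0.05).
#' @return object of class \code{composition_report}: \code{fractions}
#'   (named over all 20 residues, summing to 1), \code{cys_fraction},
#'   \code{gly_fraction}, \code{pro_fraction}, \code{is_crp},
#'   \code{length_aa}.
#' @export
composition_stats <- function(protein, crp_threshold = 0.05) {
  if (!nzchar(protein)) stop("empty protein sequence")
  ch <- strsplit(protein, "")[[1]]
  badc <- setdiff(unique(ch), AA20)
  if (length(badc))
    stop("unknown residue symbol(s): ", paste(badc, collapse = ", "))
  fr <- table(factor(ch, levels = AA20)) / length(ch)
  fr <- setNames(as.numeric(fr), AA20)
  structure(list(fractions = fr,
                 cys_fraction = fr[["C"]],
                 gly_fraction = fr[["G"]],
                 pro_fraction = fr[["P"]],
                 is_crp = fr[["C"]] >= crp_threshold,
                 length_aa = length(ch)),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("<composition_report>", x$length_aa, "aa; C", round(x$cys_fraction, 3),
      "G", round(x$gly_fraction, 3), "P", round(x$pro_fraction, 3),
      if (x$is_crp) "[CRP]" else "", "\n")
  invisible(x)
}

#' Rank non-spidroin silk constituents (SpiCE designation)
#'
#' SpiCE proteins are non-spidroin low-molecular-weight silk constituents
#' with both protein and mRNA expression. Implements the designation rule:
#' non-spidroin proteins are ranked by proteome share and retained when
#' their mRNA expression exceeds a floor (default TPM > 1); the top
#' \code{n_top} are designated.
#'
#' @param shares named proteome share vector (see
#'   \code{\link{proteome_shares}} computed per protein).
#' @param is_spidroin named logical, same names.
#' @param tpm named mRNA expression (TPM) vector.
#' @param n_top number of proteins to designate (default 4).
#' @param tpm_floor minimum TPM (default 1).
#' @return character vector of designated protein ids, ranked.
#' @export
designate_spice <- function(shares, is_spidroin, tpm, n_top = 4L,
                            tpm_floor = 1) {
  ids <- names(shares)
  keep <- ids[!is_spidroin[ids] & tpm[ids] > tpm_floor]
  keep <- keep[order(-shares[keep])]
  utils::head(keep, n_top)
}
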