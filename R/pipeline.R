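#' Pipeline run configuration
#'
#' Assembles and validates the full set of thresholds and seeds used by
#' \code{\link{run_pipeline}}. The defaults encode the reference synthetic
#' study condition: a 12-unit spidroin (450 nt NTD + 12 x 120 nt repeat
#' units + 300 nt CTD), 50x error-free short reads and 15x long reads at 8\%
#' error. Configurations round-trip losslessly through JSON
#' (\code{\link{write_run_config}} / \code{\link{read_run_config}}).
#'
#' @param ... overrides for any default field (see the function body for
#'   the full list).
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    family = "MaSp4", n_repeats = 12L, repeat_len_aa = 40L,
    flank_len = 300L,
    short_coverage = 50, read_len = 150L, short_err = 0,
    paired = FALSE, insert_mean = 500L,
    long_coverage = 15, long_mean_len = 5000L, long_err = 0.08,
    k = 31L, min_count = "auto",
    min_seed_score = 150,
    anchor_k = 51L, min_depth = 5L, min_frac = 0.8, max_len = 20000L,
    window = 300L, period_max = 150L,
    correct_k = 15L, seed_k = 15L, min_identity = 0.75,
    unit_min_identity = 0.7,
    crp_threshold = 0.05, bootstrap_B = 100L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg <- validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(cfg$min_frac > 0.5 && cfg$min_frac <= 1, "min_frac must be in (0.5, 1]")
  chk(cfg$min_depth >= 1, "min_depth must be >= 1")
  chk(identical(cfg$min_count, "auto") ||
        (is.numeric(cfg$min_count) && cfg$min_count >= 1),
      "min_count must be >= 1 or \"auto\"")
  chk(cfg$k %% 2L == 1L, "k must be odd")
  chk(cfg$short_err >= 0 && cfg$short_err <= 1, "short_err must be in [0,1]")
  chk(cfg$long_err >= 0 && cfg$long_err <= 1, "long_err must be in [0,1]")
  chk(cfg$min_identity > 0 && cfg$min_identity <= 1,
      "min_identity must be in (0,1]")
  chk(cfg$crp_threshold >= 0 && cfg$crp_threshold <= 1,
      "crp_threshold must be in [0,1]")
  chk(cfg$window >= 2L * cfg$period_max, "window must be >= 2 * period_max")
  chk(cfg$bootstrap_B >= 1, "bootstrap_B must be >= 1")
  chk(cfg$anchor_k < cfg$read_len, "anchor_k must be below read_len")
  cfg
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_fields <- c("n_repeats", "repeat_len_aa", "flank_len", "read_len",
                  "insert_mean", "long_mean_len", "k",
                  "anchor_k", "min_depth", "max_len", "window", "period_max",
                  "correct_k", "seed_k", "bootstrap_B", "seed")
  if (!identical(cfg$min_count, "auto"))
    cfg$min_count <- as.integer(cfg$min_count)
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg <- validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

pipe_log <- function(stage, ..., verbose = TRUE) {
  if (verbose) message("[", stage, "] ", ...)
}

# pick the first in-frame position at or after `pos0` (0-based), given the
# 0-based in-frame anchor `frame_anchor`
next_in_frame <- function(pos0, frame_anchor) {
  pos0 + (frame_anchor - pos0) %% 3L
}

# rotate a repeat-unit coding sequence (in steps of one codon) so that the
# translated unit shows a recognisable tail at its end; among rotations the
# one scoring most grammar motif hits (+2 for a detected tail) wins, ties
# toward the smallest rotation.
canonical_unit_rotation <- function(unit_nt, grammars = spidroin_grammars()) {
  q3 <- 3L * (nchar(unit_nt) %/% 3L)
  unit_nt <- substr(unit_nt, 1L, q3)
  best <- NULL
  for (r in seq(0L, q3 - 3L, by = 3L)) {
    rot <- paste0(substr(unit_nt, r + 1L, q3), substr(unit_nt, 1L, r))
    aa <- translate_nt(rot)
    if (grepl("*", aa, fixed = TRUE)) next
    hits <- sum(vapply(grammars, function(g)
      sum(vapply(g$core_motifs, function(m)
        length(gregexpr(m, aa, fixed = TRUE)[[1]][
          gregexpr(m, aa, fixed = TRUE)[[1]] > 0]), numeric(1))),
      numeric(1)))
    tl <- detect_tail(aa)
    sc <- hits + if (tl$kind != "none") 2 else 0
    if (is.null(best) || sc > best$sc) best <- list(sc = sc, aa = aa, r = r)
  }
  if (is.null(best)) translate_nt(unit_nt) else best$aa
}

#' Run the full spidroin curation pipeline on synthetic data
#'
#' Executes simulate -> assemble -> confirm -> catalogue on one synthetic
#' spidroin gene: builds the gene from its family grammar, simulates short
#' and long reads over the flanked coding sequence, assembles a de Bruijn
#' graph and extracts unitigs, seeds both terminal domains by homology and
#' extends each with the PWM walk until the repeat array, error-corrects
#' the long reads against the short-read spectrum, maps the (repeat-trimmed)
#' terminal candidates onto long reads requiring full-length containment,
#' derives the repeat-unit consensus from the N-side candidate's periodic
#' tail, counts repeat units per full-length read (modal count), and
#' classifies the family from the reconstructed units plus the NTD clade
#' assignment.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional directory for report and artifact files
#'   (candidates FASTA, supports TSV, JSON report).
#' @param verbose emit stage-tagged log lines.
#' @return list of class \code{silkforge_report}; includes the resolved
#'   config (reproducibility contract).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = TRUE) {
  cfg <- validate_run_config(config)
  # --- simulate ------------------------------------------------------------
  pipe_log("simulate", "family ", cfg$family, ", ", cfg$n_repeats,
           " x ", cfg$repeat_len_aa, " aa units, seed ", cfg$seed,
           verbose = verbose)
  gene <- build_gene(cfg$family, cfg$n_repeats, cfg$repeat_len_aa,
                     seed = cfg$seed)
  source_seq <- with_seed(cfg$seed + 101L, paste0(
    random_dna(cfg$flank_len), gene$cds_nt, random_dna(cfg$flank_len)))
  short <- simulate_short_reads(source_seq, cfg$short_coverage, cfg$read_len,
                                cfg$short_err, paired = cfg$paired,
                                insert_mean = cfg$insert_mean,
                                seed = cfg$seed + 1L)
  long <- simulate_long_reads(source_seq, cfg$long_coverage,
                              cfg$long_mean_len, cfg$long_err,
                              seed = cfg$seed + 2L)
  # --- assemble ------------------------------------------------------------
  graph <- build_debruijn(short, cfg$k, cfg$min_count)
  utg <- extract_unitigs(graph)
  pipe_log("assemble", length(graph$nodes), " nodes, ", length(utg),
           " unitigs", verbose = verbose)
  doms <- terminal_domains()
  seeds <- find_terminal_seeds(utg, doms, cfg$min_seed_score)
  if (!nrow(seeds)) stop("stage assemble: no terminal-domain seeds found")
  seed_n <- seeds[seeds$domain_kind == "N", ][1, ]
  seed_c <- seeds[seeds$domain_kind == "C", ][1, ]
  if (is.na(seed_n$contig_id) || is.na(seed_c$contig_id))
    stop("stage assemble: missing N or C terminal seed")
  cand_n <- extend_seed(seed_n, short, cfg$anchor_k, cfg$min_depth,
                        cfg$min_frac, cfg$max_len, "3p", cfg$window,
                        cfg$period_max, name = "N_candidate")
  cand_c <- extend_seed(seed_c, short, cfg$anchor_k, cfg$min_depth,
                        cfg$min_frac, cfg$max_len, "5p", cfg$window,
                        cfg$period_max, name = "C_candidate")
  pipe_log("assemble", "N candidate ", nchar(cand_n$consensus), " nt (",
           cand_n$halted_reason, "), C candidate ",
           nchar(cand_c$consensus), " nt (", cand_c$halted_reason, ")",
           verbose = verbose)
  ident_vs_truth <- function(cand) {
    aln <- Biostrings::pairwiseAlignment(
      cand$consensus, source_seq, type = "global-local",
      substitutionMatrix = dna_submat(), gapOpening = 5, gapExtension = 2)
    aln_rc <- Biostrings::pairwiseAlignment(
      revcomp(cand$consensus), source_seq, type = "global-local",
      substitutionMatrix = dna_submat(), gapOpening = 5, gapExtension = 2)
    max(alignment_identity(aln), alignment_identity(aln_rc))
  }
  id_n <- ident_vs_truth(cand_n)
  id_c <- ident_vs_truth(cand_c)
  # --- confirm -------------------------------------------------------------
  corrected <- correct_long_reads(long, short, cfg$correct_k, 2L)
  trim_at_boundary <- function(cand) {
    # no detected boundary: fall back to the seed-derived prefix, whose end
    # sits within k-1 of the array junction; an untrimmed periodic tail
    # would let the mapper slide by whole units
    if (is.na(cand$boundary_pos) || cand$boundary_pos < cfg$seed_k)
      substr(cand$consensus, 1L, cand$seed_len)
    else substr(cand$consensus, 1L, cand$boundary_pos)
  }
  n_fwd <- trim_at_boundary(cand_n)            # gene-forward N side
  c_fwd <- revcomp(trim_at_boundary(cand_c))   # back to gene-forward
  sup_n <- map_candidate(n_fwd, corrected, cfg$seed_k, cfg$min_identity,
                         name = "N_candidate")
  sup_c <- map_candidate(c_fwd, corrected, cfg$seed_k, cfg$min_identity,
                         name = "C_candidate")
  sup <- flag_full_length(sup_n, sup_c)
  full_ids <- unique(sup$read_id[sup$full_length])
  pipe_log("confirm", nrow(sup_n), "+", nrow(sup_c), " supports, ",
           length(full_ids), " full-length reads", verbose = verbose)
  # --- repeat-unit consensus from the N-side periodic tail ----------------
  q <- cand_n$boundary_period
  modal_count <- NA_integer_
  unit_aa <- NA_character_
  if (!is.na(cand_n$boundary_pos) && !is.na(q)) {
    # reading frame anchor: NTD hit start on the oriented consensus
    ctg_len <- nchar(seed_n$contig_seq)
    ostart <- if (identical(seed_n$strand, "-"))
      ctg_len - seed_n$hit_end else seed_n$hit_start
    q3 <- 3L * as.integer(round(q / 3))
    # take the unit one full period inside the array: the detected boundary
    # can sit up to ~a window-edge early, but boundary + q is always clean
    # when the consensus carries at least two periods past the boundary
    u0 <- cand_n$boundary_pos
    if (nchar(cand_n$consensus) >= u0 + 2L * q3 + 3L) u0 <- u0 + q3
    ustart <- next_in_frame(u0, ostart %% 3L)
    unit_nt <- substr(cand_n$consensus, ustart + 1L, ustart + q3)
    if (nchar(unit_nt) == q3 && q3 >= 21L) {
      unit_aa <- canonical_unit_rotation(unit_nt)
      counts <- integer(0)
      for (id in full_ids) {
        a <- sup_n[sup_n$read_id == id, ][1, ]
        b <- sup_c[sup_c$read_id == id, ][1, ]
        rseq <- corrected$reads$seq[corrected$reads$id == id]
        if (a$strand == "-") rseq <- revcomp(rseq)
        L <- nchar(rseq)
        # small margins absorb trimming slack at the candidate edges while
        # keeping the first tiling window anchored on a clean unit copy
        mg <- q3 %/% 6L
        seg <- if (a$strand == "+")
          substr(rseq, max(1L, a$read_end + 1L - mg),
                 min(L, b$read_start + mg))
        else substr(rseq, max(1L, L - a$read_start + 1L - mg),
                    min(L, L - b$read_end + mg))
        if (nchar(seg) >= q3)
          counts <- c(counts, count_repeat_units(seg, unit_nt,
                                                 cfg$unit_min_identity))
      }
      if (length(counts)) {
        tab <- table(counts)
        modal_count <- as.integer(names(tab)[which.max(tab)])
      }
    }
  }
  # --- catalogue -----------------------------------------------------------
  family <- "other"; conflict <- NA; scores <- NULL
  ntd_assign <- sub("_NTD$", "", seed_n$domain_name)
  if (!is.na(unit_aa) && !is.na(modal_count)) {
    units <- rep(list(unit_aa), max(modal_count, 1L))
    cls <- classify_family(units, ntd_assignment = ntd_assign)
    family <- cls$family; conflict <- cls$conflict; scores <- cls$scores
  }
  pipe_log("catalogue", "modal repeat count ", modal_count, ", family ",
           family, verbose = verbose)
  report <- structure(list(
    config = cfg,
    truth = list(family = gene$family, n_repeats = cfg$n_repeats,
                 cds_len = nchar(gene$cds_nt)),
    candidates = data.frame(
      name = c("N_candidate", "C_candidate"),
      length = c(nchar(cand_n$consensus), nchar(cand_c$consensus)),
      halted_reason = c(cand_n$halted_reason, cand_c$halted_reason),
      boundary_pos = c(cand_n$boundary_pos, cand_c$boundary_pos),
      identity_vs_truth = c(id_n, id_c), stringsAsFactors = FALSE),
    supports = sup, n_full_length = length(full_ids),
    modal_repeat_count = modal_count, repeat_unit_aa = unit_aa,
    ntd_assignment = ntd_assign,
    family = family, conflict = conflict, scores = scores,
    candidate_n = cand_n, candidate_c = cand_c),
    class = "silkforge_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(c(N_candidate = cand_n$consensus,
                  C_candidate = cand_c$consensus),
                file.path(out_dir, "candidates.fasta"))
    write.table(sup, file.path(out_dir, "supports.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(cfg),
           candidates = report$candidates,
           n_full_length = report$n_full_length,
           modal_repeat_count = report$modal_repeat_count,
           family = report$family, conflict = report$conflict),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  report
}

#' @export
print.silkforge_report <- function(x, ...) {
  cat("<silkforge_report>\n")
  cat("  truth: family", x$truth$family, "with", x$truth$n_repeats,
      "repeat units; CDS", x$truth$cds_len, "nt\n")
  print(x$candidates[, c("name", "length", "halted_reason",
                         "identity_vs_truth")])
  cat("  full-length long reads:", x$n_full_length,
      "| modal repeat count:", x$modal_repeat_count, "\n")
  cat("  classified family:", x$family,
      if (isTRUE(x$conflict)) "(NTD conflict)" else "", "\n")
  invisible(x)
}
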