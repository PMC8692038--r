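#' Spidroin repeat-motif grammars
#'
#' Returns the packaged grammar table describing, for each spidroin family,
#' the diagnostic core motifs of its repetitive units and the rule governing
#' the unit tail (the block that ends a repeat unit: a poly-alanine run, a
#' poly-GA run, a poly-X stretch of neutral residues, or no tail at all).
#'
#' The grammar covers the Caerostris-type families: MaSp2 uses GPGSQ motifs
#' (the canonical araneid GPGQQ with QQ relaxed to SQ); MaSp4 replaces the
#' MaSp2 core with GPGPQ and carries a VSVVSTTVS poly-X tail instead of
#' poly-A; MaSp5 shows only tandem GGLGGSG/GSGGR motifs with no tail; MaSp3
#' carries SGGRGGY (the araneid DGGRGGY with D relaxed to S); MaSp1 mixes
#' poly-A with SSSVAISL / ISISAAAS tail motifs; the three MiSp subfamilies
#' share cores and differ by tail class (MiSp1B poly-A, MiSp1D poly-GA,
#' MiSp1C poly-X); Flag uses GPGG-type elastic motifs. Entries beyond the
#' motifs reported for Caerostris are reconstructed from field-standard
#' spidroin motifs; treat the table as editable.
#'
#' @param family optional family label; when given, the single grammar for
#'   that family is returned (error naming valid labels otherwise).
#' @return a named list of \code{motif_grammar} objects (or one such object),
#'   each with fields \code{family}, \code{core_motifs}, \code{tail_rule}
#'   (character vector; first entry is the primary rule), \code{tail_motifs},
#'   \code{clade} and \code{notes}.
#' @export
spidroin_grammars <- function(family = NULL) {
  g <- function(family, core, tail_rule, tail_motifs = character(0),
                clade, notes = "") {
    structure(list(family = family, core_motifs = core,
                   tail_rule = tail_rule, tail_motifs = tail_motifs,
                   clade = clade, notes = notes),
              class = "motif_grammar")
  }
  grams <- list(
    MaSp1 = g("MaSp1", c("GGAGQG", "GGQGAG"), "poly_A",
              c("SSSVAISL", "ISISAAAS"), "MaSp1",
              "poly-A tails interleaved with SSSVAISL/ISISAAAS blocks"),
    MaSp2 = g("MaSp2", c("GPGSQ", "GPGQQ"), "poly_A", character(0), "MaSp2",
              "GPGQQ diglutamine relaxed to SQ in Caerostris"),
    MaSp3 = g("MaSp3", c("SGGRGGY", "DGGRGGY"), "poly_A", character(0),
              "MaSp3", "araneid DGGRGGY with D substituted by S"),
    MaSp4 = g("MaSp4", "GPGPQ", "poly_X", "VSVVSTTVS", "MaSp2",
              "no poly-A; neutral-residue VSVVSTTVS tail; MaSp2 clade NTD"),
    MaSp5 = g("MaSp5", c("GGLGGSG", "GSGGR"), "none", character(0), "MaSp5",
              "tandem motifs only, no tail portion"),
    MiSp1B = g("MiSp1B", c("GGYGQGG", "GAGGA"), c("poly_A", "poly_GA"),
               character(0), "MiSp", "typical MiSp poly-A/GA tail"),
    MiSp1C = g("MiSp1C", c("GGYGQGG", "GAGGA"), "poly_X", "SVSTTIS",
               "MiSp", "alternative poly-X tail"),
    MiSp1D = g("MiSp1D", c("GGYGQGG", "GAGGA"), c("poly_GA", "poly_A"),
               character(0), "MiSp", "typical MiSp poly-A/GA tail"),
    Flag = g("Flag", c("GPGGS", "GPGGY"), "none", character(0), "Flag",
             "elastic GPGG-type motifs")
  )
  if (is.null(family)) return(grams)
  if (!family %in% names(grams))
    stop("unknown family label '", family, "'; valid labels: ",
         paste(names(grams), collapse = ", "))
  grams[[family]]
}

#' @export
print.motif_grammar <- function(x, ...) {
  cat("<motif_grammar>", x$family, "(clade", paste0(x$clade, ")"), "\n")
  cat("  core motifs:", paste(x$core_motifs, collapse = ", "), "\n")
  cat("  tail rule:  ", paste(x$tail_rule, collapse = " | "),
      if (length(x$tail_motifs))
        paste0("(motifs: ", paste(x$tail_motifs, collapse = ", "), ")")
      else "", "\n")
  invisible(x)
}

# clade for a family or clade label
family_clade <- function(label) {
  grams <- spidroin_grammars()
  if (label %in% names(grams)) return(grams[[label]]$clade)
  clades <- unique(vapply(grams, `[[`, "", "clade"))
  if (label %in% clades) return(label)
  NA_character_
}
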