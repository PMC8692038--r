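#' Synthetic terminal-domain reference set
#'
#' Spidroins are flanked by conserved, phylogenetically informative
#' N-terminal and C-terminal domains (NTD/CTD). The real Caerostris terminal
#' domains are not redistributed with this package; instead a synthetic
#' reference set is generated deterministically: one ancestral sequence per
#' domain kind, diverged into clade sequences (MaSp1, MaSp2, MaSp3, MaSp5,
#' MiSp, Flag) and then into per-family sequences, so that within-clade
#' identity stays above 70\% while clades remain well separated. NTDs are
#' 150 aa (450 nt of coding sequence) and CTDs 100 aa (300 nt).
#'
#' \code{make_terminal_domains()} regenerates the set from its fixed internal
#' seed; \code{terminal_domains()} reads the versioned copy shipped under
#' \code{inst/extdata/terminal_domains_synthetic.fasta} (they are identical).
#' Sequence names follow the \code{<family>_NTD} / \code{<family>_CTD}
#' convention used by \code{\link{find_terminal_seeds}}.
#'
#' @return named character vector of amino-acid sequences.
#' @export
make_terminal_domains <- function() {
  mutate_aa <- function(seq, rate) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    idx <- which(runif(n) < rate)
    for (i in idx) {
      alt <- setdiff(AA20, ch[i])
      ch[i] <- alt[sample.int(length(alt), 1L)]
    }
    paste0(ch, collapse = "")
  }
  with_seed(760241L, {
    clades <- c("MaSp1", "MaSp2", "MaSp3", "MaSp5", "MiSp", "Flag")
    fam_of <- list(MaSp1 = "MaSp1", MaSp2 = c("MaSp2", "MaSp4"),
                   MaSp3 = "MaSp3", MaSp5 = "MaSp5",
                   MiSp = c("MiSp1B", "MiSp1C", "MiSp1D"), Flag = "Flag")
    out <- character(0)
    for (kind in c("NTD", "CTD")) {
      len <- if (kind == "NTD") 150L else 100L
      root <- paste0(c("M", sample(AA20, len - 1L, replace = TRUE)),
                     collapse = "")
      for (cl in clades) {
        clseq <- mutate_aa(root, 0.45)
        for (fam in fam_of[[cl]]) {
          s <- mutate_aa(clseq, 0.10)
          if (kind == "NTD") s <- paste0("M", substr(s, 2L, len))
          out[paste0(fam, "_", kind)] <- s
        }
      }
    }
    out
  })
}

#' @rdname make_terminal_domains
#' @export
terminal_domains <- function() {
  path <- system.file("extdata", "terminal_domains_synthetic.fasta",
                      package = "silkforge")
  if (!nzchar(path)) return(make_terminal_domains())
  read_fasta(path)
}
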