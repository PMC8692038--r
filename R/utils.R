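#' @import Biostrings
#' @importFrom stats median rnorm runif rgamma lm coef setNames
#' @importFrom utils write.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T/N).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a coding nucleotide sequence
#'
#' @param nt character vector of in-frame coding sequences (length divisible
#'   by 3).
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     if.fuzzy.codon = "X"))
}

# aa -> synonymous codon table, built once from the standard genetic code
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

# Reverse-translate an amino-acid string, sampling uniformly among
# synonymous codons (uses the current RNG stream).
reverse_translate <- function(aa) {
  if (nchar(aa) == 0L) return("")
  tab <- codon_table()
  res <- vapply(strsplit(aa, "")[[1]], function(a) {
    cods <- tab[[a]]
    if (is.null(cods)) stop("cannot reverse-translate residue '", a, "'")
    cods[sample.int(length(cods), 1L)]
  }, character(1))
  paste0(res, collapse = "")
}

random_dna <- function(n) {
  paste0(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

# All k-mers of a single sequence as a character vector (empty if too short).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Canonical form: lexicographic min of k-mer and its reverse complement.
canonical_kmers <- function(km) {
  if (length(km) == 0L) return(character(0))
  rc <- revcomp(km)
  ifelse(km <= rc, km, rc)
}

# Trapezoid integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Nucleotide scoring matrix for DNA pairwise alignment, cached.
dna_submat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = TRUE)
    m
  }
})

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Fraction of identical columns among columns where neither sequence gaps.
alignment_identity <- function(aln) {
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- pa != "-" & sa != "-"
  if (!any(keep)) return(0)
  mean(pa[keep] == sa[keep])
}
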