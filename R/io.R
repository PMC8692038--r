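#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings that enforce the package's contracts:
#' sequences are uppercased on read, multi-line wrapping and CRLF endings
#' are handled, duplicate ids raise an error naming the duplicates, and
#' empty sequences are rejected.
#'
#' @param path file path.
#' @param records named character vector of sequences.
#' @param width line-wrap width on write.
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  setNames(seqs, ids)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (length(records) == 0L) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named")
  if (any(!nzchar(records))) stop("empty sequence in records")
  Biostrings::writeXStringSet(Biostrings::BStringSet(records), path,
                              width = width)
  invisible(path)
}

#' Read and write FASTQ files (Sanger Phred+33)
#'
#' \code{write_fastq} serialises a \code{\link{read_set}} (origin truth is
#' not part of the FASTQ and is written separately, see
#' \code{\link{write_truth_tsv}}). \code{read_fastq} parses the file back
#' into a \code{read_set} without truth.
#'
#' @param rs a \code{\link{read_set}}.
#' @param path file path.
#' @param platform platform label to attach on read.
#' @return \code{read_fastq}: a \code{read_set}.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  qual <- ifelse(is.na(rs$reads$qual),
                 vapply(nchar(rs$reads$seq), function(n) strrep("I", n), ""),
                 rs$reads$qual)
  lines <- as.vector(rbind(paste0("@", rs$reads$id), rs$reads$seq,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path, platform = c("short", "long")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  ids <- sub("\\s.*$", "", ids)
  reads <- data.frame(id = ids,
                      seq = toupper(lines[seq(2, length(lines), 4)]),
                      qual = lines[seq(4, length(lines), 4)],
                      mate = NA_character_, stringsAsFactors = FALSE)
  read_set(reads, platform)
}

#' Write a read-origin truth table
#'
#' TSV with columns \code{id}, \code{start}, \code{end} (0-based half-open
#' on the source sequence) and \code{strand}.
#'
#' @param rs a \code{\link{read_set}} with truth.
#' @param path file path.
#' @export
write_truth_tsv <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"), !is.null(rs$truth))
  write.table(rs$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric numeric matrix with row names.
#' @param path file path.
#' @export
write_phylip_dm <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  invisible(path)
}
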