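#' Extract the N-terminal region of spidroins
#'
#' Spidroin phylogenies are built from the first 100 N-terminal amino acid
#' residues, the conserved and alignable part of the protein. Sequences
#' shorter than \code{n} are returned whole and flagged.
#'
#' @param proteins character vector of amino-acid sequences (optionally
#'   named).
#' @param n number of residues (default 100).
#' @return character vector of regions with logical attribute
#'   \code{"flagged"} marking sequences shorter than \code{n} (or with
#'   \code{n = 0}, where the region is empty).
#' @export
n_terminal_region <- function(proteins, n = 100L) {
  if (any(!nzchar(proteins))) stop("empty protein sequence")
  out <- substr(proteins, 1L, n)
  names(out) <- names(proteins)
  attr(out, "flagged") <- nchar(proteins) < n | n == 0L
  out
}

#' Pairwise alignment distance between two protein sequences
#'
#' Global alignment with affine gaps (BLOSUM62, gap open 10, extend 1);
#' the distance is 1 minus the fraction of identical columns among aligned
#' columns where neither sequence gaps (a p-distance on the induced
#' pairwise alignment). Symmetric by construction.
#'
#' @param a,b amino-acid sequences.
#' @return numeric distance in [0, 1].
#' @export
align_and_distance <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  # align in canonical order so tie-broken alignments cannot break symmetry
  p <- if (a <= b) a else b
  s <- if (a <= b) b else a
  aln <- Biostrings::pairwiseAlignment(
    p, s, type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 1)
  1 - alignment_identity(aln)
}

#' Pairwise distance matrix for a set of sequences
#'
#' @param seqs named character vector of amino-acid sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- align_and_distance(seqs[[i]], seqs[[j]])
    }
  d
}

#' Neighbor-joining tree construction
#'
#' Canonical Saitou-Nei neighbor joining: at each step the pair minimising
#' the Q criterion \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} is joined, with
#' branch lengths \eqn{l_i = d_{ij}/2 + (r_i - r_j)/(2(n-2))}, until three
#' clusters remain and the final star is resolved in closed form. Ties in Q
#' are broken deterministically toward the lowest index pair. Negative
#' branch lengths at a join are clamped to zero with the deficit moved to
#' the sibling edge (so the pair's length sum is preserved); at the final
#' star, negative lengths are clamped to zero.
#'
#' With exactly two taxa the result is the single split with the distance
#' shared equally. For an exactly additive (tree-metric) input the output
#' reproduces the generating topology and branch lengths.
#'
#' @param D symmetric distance matrix with row names (or a \code{dist}).
#' @return an unrooted tree of class \code{phylo} (ape).
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  fm <- function(x) sprintf("%.17g", max(x, 0))
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labs[1],
                                        fm(D[1, 2] / 2), labs[2],
                                        fm(D[1, 2] / 2)))
    return(tr)
  }
  d <- D
  frag <- labs
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- t(apply(idx, 1L, sort))
    idx <- unique(idx)
    ord <- order(idx[, 1], idx[, 2])
    i <- idx[ord[1], 1]; j <- idx[ord[1], 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- d[i, j]; li <- 0 }
    if (lj < 0) { li <- d[i, j]; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fm(li), frag[j], fm(lj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    dimnames(d2) <- NULL
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fm(la), frag[2], fm(lb),
                 frag[3], fm(lc))
  ape::read.tree(text = nwk)
}

#' Canonical bipartition keys of an unrooted tree
#'
#' Each internal edge splits the taxa into two sets; the split is keyed by
#' the sorted labels of the side not containing the alphabetically first
#' taxon. Trivial (single-leaf) splits are excluded.
#'
#' @param phy a \code{phylo} tree.
#' @return character vector of split keys.
#' @export
tree_splits <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  ref <- sort(labs)[1]
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (ref %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  keys <- keys[vapply(keys, function(k)
    length(strsplit(k, "|", fixed = TRUE)[[1]]) >= 2, logical(1))]
  n <- length(labs)
  keys[vapply(strsplit(keys, "|", fixed = TRUE),
              function(s) length(s) <= n - 2L, logical(1))]
}

# p-distance matrix from an alignment column matrix (taxa x columns),
# excluding columns where either sequence gaps; 1 when nothing aligns.
pdist_from_columns <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n > 1L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      keep <- mat[i, ] != "-" & mat[j, ] != "-"
      d[i, j] <- d[j, i] <- if (!any(keep)) 1 else
        mean(mat[i, keep] != mat[j, keep])
    }
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' The point-estimate tree is built from pairwise global-alignment distances
#' (\code{\link{distance_matrix}} + \code{\link{neighbor_joining}}). For
#' bootstrap resampling the sequences are stacked into a pseudo-alignment
#' (padded to the longest sequence with terminal gaps), columns are
#' resampled with replacement \code{B} times, and each replicate tree is
#' rebuilt from p-distances on the resampled columns. Support for each
#' internal edge of the point tree is the percentage of replicates
#' containing the same bipartition, attached as node labels.
#'
#' This stacked-padding stage is a deliberate methodological substitution
#' for progressive multiple alignment, which is out of scope; it is exact
#' when the input regions have equal length (the usual case for fixed-length
#' N-terminal regions).
#'
#' @param sequences named character vector of N-terminal regions (>= 4).
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed (deterministic for a fixed seed).
#' @return a \code{phylo} tree; internal node labels carry support
#'   percentages (0-100), and the per-edge table is attached as attribute
#'   \code{"support"}.
#' @export
bootstrap_support <- function(sequences, B = 100L, seed = 1L) {
  stopifnot(length(sequences) >= 4L, B >= 1L)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("t", seq_along(sequences))
  pt <- neighbor_joining(distance_matrix(sequences))
  L <- max(nchar(sequences))
  padded <- vapply(sequences, function(s)
    paste0(s, strrep("-", L - nchar(s))), "")
  mat <- do.call(rbind, strsplit(padded, ""))
  rownames(mat) <- names(sequences)
  keys <- tree_splits(pt)
  hits <- setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(L, L, replace = TRUE)
      db <- pdist_from_columns(mat[, cols, drop = FALSE])
      tb <- neighbor_joining(db)
      kb <- tree_splits(tb)
      hits[keys %in% kb] <- hits[keys %in% kb] + 1
    }
  })
  support <- round(100 * hits / B)
  # attach as node labels: match each internal node's split to its key
  pp <- ape::prop.part(pt)
  labs <- attr(pp, "labels")
  ref <- sort(labs)[1]
  node_keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (ref %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  pt$node.label <- ifelse(node_keys %in% names(support),
                          as.character(support[node_keys]), "")
  attr(pt, "support") <- data.frame(split = names(support),
                                    support = as.numeric(support),
                                    stringsAsFactors = FALSE)
  pt
}
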