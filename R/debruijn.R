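#' Build a de Bruijn graph from short reads
#'
#' Nodes are canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement) with coverage counts; edges are (k-1)-overlap links
#' derived from (k+1)-mers, carried with the orientation of each endpoint so
#' the graph is bidirected. k-mers containing N are skipped, and nodes below
#' \code{min_count} (with their incident edges) are removed. k must be odd
#' so that no k-mer is its own reverse complement.
#'
#' @param reads a \code{\link{read_set}} or character vector of read
#'   sequences.
#' @param k odd k-mer size, smaller than the shortest read.
#' @param min_count minimum canonical k-mer count for a node to be kept, or
#'   \code{"auto"} to place the cutoff at the first valley of the k-mer
#'   count histogram (separating the sequencing-error mode from the true
#'   coverage mode, as in standard k-mer spectrum filtering).
#' @return object of class \code{debruijn_graph}: \code{k}, \code{nodes}
#'   (named integer vector of counts) and \code{edges} (data.frame with
#'   \code{from}, \code{from_or}, \code{to}, \code{to_or}, \code{count};
#'   both directions of every link are present).
#' @export
build_debruijn <- function(reads, k = 31L, min_count = 2L) {
  if (inherits(reads, "read_set")) reads <- reads$reads$seq
  k <- as.integer(k)
  if (k %% 2L == 0L)
    stop("k must be odd (even k admits reverse-complement palindromes)")
  km <- unlist(lapply(reads, seq_kmers, k = k), use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0L)
    return(structure(list(k = k, nodes = setNames(integer(0), character(0)),
                          edges = empty_edges()), class = "debruijn_graph"))
  canon <- canonical_kmers(km)
  cnt <- table(canon)
  nodes <- setNames(as.integer(cnt), names(cnt))
  if (identical(min_count, "auto")) {
    h <- tabulate(nodes)
    valley <- 1L
    while (valley < length(h) && h[valley + 1L] < h[valley]) valley <- valley + 1L
    min_count <- if (valley >= length(h)) 2L else valley + 1L
  }
  nodes <- nodes[nodes >= min_count]

  ek <- unlist(lapply(reads, seq_kmers, k = k + 1L), use.names = FALSE)
  ek <- ek[!grepl("N", ek, fixed = TRUE)]
  edges <- empty_edges()
  if (length(ek)) {
    ecnt <- table(ek)
    ekm <- names(ecnt)
    a <- substr(ekm, 1L, k); b <- substr(ekm, 2L, k + 1L)
    ca <- canonical_kmers(a); cb <- canonical_kmers(b)
    oa <- ifelse(a == ca, "+", "-"); ob <- ifelse(b == cb, "+", "-")
    keep <- ca %in% names(nodes) & cb %in% names(nodes)
    if (any(keep)) {
      fwd <- data.frame(from = ca[keep], from_or = oa[keep],
                        to = cb[keep], to_or = ob[keep],
                        count = as.integer(ecnt)[keep],
                        stringsAsFactors = FALSE)
      rev <- data.frame(from = fwd$to, from_or = flip_or(fwd$to_or),
                        to = fwd$from, to_or = flip_or(fwd$from_or),
                        count = fwd$count, stringsAsFactors = FALSE)
      edges <- rbind(fwd, rev)
      key <- paste(edges$from, edges$from_or, edges$to, edges$to_or)
      agg <- tapply(edges$count, key, sum)
      first <- !duplicated(key)
      edges <- edges[first, , drop = FALSE]
      edges$count <- as.integer(agg[paste(edges$from, edges$from_or,
                                          edges$to, edges$to_or)])
      edges <- edges[order(edges$from, edges$from_or, edges$to, edges$to_or),
                     , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(k = k, nodes = nodes, edges = edges),
            class = "debruijn_graph")
}

empty_edges <- function() {
  data.frame(from = character(0), from_or = character(0),
             to = character(0), to_or = character(0), count = integer(0),
             stringsAsFactors = FALSE)
}

flip_or <- function(x) ifelse(x == "+", "-", "+")

#' @export
print.debruijn_graph <- function(x, ...) {
  cat("<debruijn_graph> k =", x$k, ";", length(x$nodes), "nodes,",
      nrow(x$edges) / 2, "links\n")
  invisible(x)
}

oriented_seq <- function(node, orient) {
  if (orient == "+") node else revcomp(node)
}

#' Extract unitigs from a de Bruijn graph
#'
#' Unitigs are the maximal non-branching paths of the bidirected graph.
#' Each is reported once, in canonical orientation (lexicographic minimum
#' of the sequence and its reverse complement), sorted by length descending
#' then lexicographically.
#'
#' @param graph a \code{debruijn_graph}.
#' @return character vector of contig sequences (named utg00001, ...).
#' @export
extract_unitigs <- function(graph) {
  stopifnot(inherits(graph, "debruijn_graph"))
  if (length(graph$nodes) == 0L) return(setNames(character(0), character(0)))
  keys <- paste(graph$edges$from, graph$edges$from_or)
  succ <- split(paste(graph$edges$to, graph$edges$to_or), keys)
  succ <- lapply(succ, function(v) sort(unique(v)))
  succ_env <- list2env(succ, hash = TRUE, parent = emptyenv())
  out1 <- function(key) {
    v <- succ_env[[key]]
    if (is.null(v) || length(v) != 1L) NA_character_ else v
  }
  flip_key <- function(key) {
    sp <- strsplit(key, " ", fixed = TRUE)[[1]]
    paste(sp[1], flip_or(sp[2]))
  }
  all_keys <- sort(c(paste(names(graph$nodes), "+"),
                     paste(names(graph$nodes), "-")))
  # an oriented node can be entered uniquely if its reverse has one
  # successor whose reverse in turn has one successor
  has_unique_pred <- function(key) {
    back <- out1(flip_key(key))
    if (is.na(back)) return(FALSE)
    !is.na(out1(flip_key(back)))
  }
  visited <- new.env(hash = TRUE, parent = emptyenv())
  seen <- function(key) !is.null(visited[[key]])
  mark <- function(key) { visited[[key]] <- TRUE; visited[[flip_key(key)]] <- TRUE }
  walk <- function(start) {
    chain <- start
    in_chain <- new.env(hash = TRUE, parent = emptyenv())
    in_chain[[start]] <- TRUE
    in_chain[[flip_key(start)]] <- TRUE
    cur <- start
    repeat {
      nxt <- out1(cur)
      if (is.na(nxt)) break
      if (is.na(out1(flip_key(nxt)))) break    # next has multiple preds
      if (!is.null(in_chain[[nxt]])) break     # cycle or palindrome fold
      if (seen(nxt)) break
      chain <- c(chain, nxt)
      in_chain[[nxt]] <- TRUE
      in_chain[[flip_key(nxt)]] <- TRUE
      cur <- nxt
    }
    chain
  }
  chain_seq <- function(chain) {
    parts <- strsplit(chain, " ", fixed = TRUE)
    s <- oriented_seq(parts[[1]][1], parts[[1]][2])
    if (length(chain) > 1L)
      s <- paste0(s, paste0(vapply(parts[-1], function(p) {
        os <- oriented_seq(p[1], p[2])
        substr(os, graph$k, graph$k)
      }, character(1)), collapse = ""))
    s
  }
  contigs <- character(0)
  starts <- all_keys[!vapply(all_keys, has_unique_pred, logical(1))]
  for (st in starts) {
    if (seen(st)) next
    ch <- walk(st)
    for (key in ch) mark(key)
    contigs <- c(contigs, chain_seq(ch))
  }
  for (st in all_keys) {            # leftover cycles
    if (seen(st)) next
    ch <- walk(st)
    for (key in ch) mark(key)
    contigs <- c(contigs, chain_seq(ch))
  }
  rc <- revcomp(contigs)
  contigs <- unique(ifelse(contigs <= rc, contigs, rc))
  contigs <- contigs[order(-nchar(contigs), contigs)]
  setNames(contigs, sprintf("utg%05d", seq_along(contigs)))
}
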