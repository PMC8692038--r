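test_that("N-terminal regions truncate at 100 residues and flag short input", {
  p <- random_protein(250, seed = 301)
  r <- n_terminal_region(p)
  expect_identical(nchar(r[1]), 100L)
  expect_identical(r[1], substr(p, 1, 100))
  expect_false(attr(r, "flagged")[1])

  short <- n_terminal_region(random_protein(60, seed = 302))
  expect_identical(nchar(short[1]), 60L)
  expect_true(attr(short, "flagged")[1])

  z <- n_terminal_region(p, n = 0)
  expect_identical(nchar(z[1]), 0L)
  expect_true(attr(z, "flagged")[1])
})

test_that("alignment distance is a p-distance on aligned columns", {
  a <- random_protein(100, seed = 303)
  expect_identical(align_and_distance(a, a), 0)
  b <- a
  substr(b, 50, 50) <- if (substr(a, 50, 50) == "W") "Y" else "W"
  expect_equal(align_and_distance(a, b), 0.01)
  # symmetry over random pairs
  sym <- silkforge:::with_seed(304L, vapply(1:25, function(i) {
    x <- paste0(sample(AA, 80, TRUE), collapse = "")
    y <- paste0(sample(AA, 90, TRUE), collapse = "")
    abs(align_and_distance(x, y) - align_and_distance(y, x))
  }, numeric(1)))
  expect_true(all(sym < 1e-12))
})

test_that("distance matrices satisfy the metric axioms tested", {
  seqs <- setNames(vapply(1:5, function(i) random_protein(60, seed = 310 + i),
                          ""), paste0("t", 1:5))
  D <- distance_matrix(seqs)
  expect_identical(unname(diag(D)), rep(0, 5))
  expect_lt(max(abs(D - t(D))), 1e-12)
  expect_true(all(is.finite(D)) && all(D >= 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0.5);")
  D <- ape::cophenetic.phylo(tr)
  out <- neighbor_joining(D)
  expect_setequal(tree_splits(out), tree_splits(ape::unroot(tr)))
  expect_lt(max(abs(ape::cophenetic.phylo(out)[rownames(D), colnames(D)] - D)),
            1e-12)

  # three taxa: unique star with closed-form lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$edge.length), c(0.5, 1.5, 2.5))

  # two taxa: single split of the distance
  t2 <- neighbor_joining(matrix(c(0, 3, 3, 0), 2, 2,
                                dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(t2$edge.length, c(1.5, 1.5))
})

test_that("NJ matches the independent implementation on random additive trees", {
  silkforge:::with_seed(305L, {
    for (i in 1:25) {
      tr <- random_additive_tree(sample(6:10, 1))
      D <- ape::cophenetic.phylo(tr)
      mine <- neighbor_joining(D)
      ref <- ape::nj(D)                       # independent oracle
      expect_setequal(tree_splits(mine), tree_splits(ape::unroot(tr)))
      expect_setequal(tree_splits(mine), tree_splits(ref))
      expect_lt(max(abs(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)]
                        - D)), 1e-9)
    }
  })
})

test_that("newick round trip preserves topology, lengths and supports", {
  seqs <- silkforge:::with_seed(306L, {
    base1 <- paste0(sample(AA, 100, TRUE), collapse = "")
    base2 <- mutate_protein(base1, 50)
    c(a1 = mutate_protein(base1, 2), a2 = mutate_protein(base1, 2),
      b1 = mutate_protein(base2, 2), b2 = mutate_protein(base2, 2))
  })
  bt <- bootstrap_support(seqs, B = 25, seed = 9)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(bt, path)
  back <- ape::read.tree(path)
  expect_setequal(tree_splits(back), tree_splits(bt))
  o <- match(back$tip.label, bt$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[bt$tip.label, bt$tip.label],
               ape::cophenetic.phylo(bt)[bt$tip.label, bt$tip.label],
               tolerance = 1e-9)
  expect_identical(sort(back$node.label), sort(bt$node.label))
})

test_that("bootstrap support is deterministic and degenerate at B = 1", {
  seqs <- silkforge:::with_seed(307L, {
    base1 <- paste0(sample(AA, 100, TRUE), collapse = "")
    base2 <- mutate_protein(base1, 50)
    c(a1 = mutate_protein(base1, 1), a2 = mutate_protein(base1, 1),
      b1 = mutate_protein(base2, 1), b2 = mutate_protein(base2, 1))
  })
  b1 <- bootstrap_support(seqs, B = 1, seed = 4)
  expect_true(all(attr(b1, "support")$support %in% c(0, 100)))
  r1 <- bootstrap_support(seqs, B = 20, seed = 11)
  r2 <- bootstrap_support(seqs, B = 20, seed = 11)
  expect_identical(attr(r1, "support"), attr(r2, "support"))
})

test_that("packaged terminal domains cluster by clade in the NJ tree", {
  doms <- terminal_domains()
  ntds <- doms[grepl("_NTD$", names(doms))]
  names(ntds) <- sub("_NTD$", "", names(ntds))
  tr <- neighbor_joining(distance_matrix(n_terminal_region(ntds)))
  splits <- tree_splits(tr)
  expect_true("MaSp2|MaSp4" %in% splits)
  misp <- paste(sort(c("MiSp1B", "MiSp1C", "MiSp1D")), collapse = "|")
  expect_true(misp %in% splits ||
                paste(sort(setdiff(names(ntds),
                                   c("MiSp1B", "MiSp1C", "MiSp1D"))),
                      collapse = "|") %in% splits)
})
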