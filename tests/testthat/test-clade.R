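test_that("family selection is exact-tag with metadata carried through", {
  ann <- data.frame(seq_id = c("p1", "p2", "p3"),
                    tag = c("COG0841", "COG0841", "COG1132"),
                    genome_id = c("g1", "g1", "g2"),
                    stringsAsFactors = FALSE)
  fam <- select_family(ann, "COG0841")
  expect_identical(fam$seq_id, c("p1", "p2"))
  expect_identical(fam$genome_id, c("g1", "g1"))
  expect_error(select_family(ann, "COG9999"), "no proteins")
})

test_that("alignment dissimilarity matches an independent DP oracle", {
  seqs <- c(a = "HEAGAWGHEE", b = "PAWHEAE")
  D <- pairwise_distance(seqs)
  sub <- blosum50()
  s_ab <- oracle_global_score("HEAGAWGHEE", "PAWHEAE", sub)
  s_aa <- sum(sub[cbind(strsplit(seqs[["a"]], "")[[1]],
                        strsplit(seqs[["a"]], "")[[1]])])
  s_bb <- sum(sub[cbind(strsplit(seqs[["b"]], "")[[1]],
                        strsplit(seqs[["b"]], "")[[1]])])
  expect_equal(D["a", "b"], 1 - s_ab / min(s_aa, s_bb))

  # identical sequences have distance zero; random pairs are symmetric
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rnd <- vapply(1:4, function(i) {
    paste(sample(aa, 30, replace = TRUE), collapse = "")
  }, character(1))
  names(rnd) <- paste0("r", 1:4)
  rnd <- c(rnd, r1copy = unname(rnd[1]))
  D2 <- pairwise_distance(rnd)
  expect_equal(D2["r1", "r1copy"], 0)
  expect_equal(D2, t(D2))
  expect_true(all(diag(D2) == 0))
  # oracle agreement on one random pair
  s12 <- oracle_global_score(rnd[["r1"]], rnd[["r2"]], sub)
  s11 <- sum(sub[cbind(strsplit(rnd[["r1"]], "")[[1]],
                       strsplit(rnd[["r1"]], "")[[1]])])
  s22 <- sum(sub[cbind(strsplit(rnd[["r2"]], "")[[1]],
                       strsplit(rnd[["r2"]], "")[[1]])])
  expect_equal(D2["r1", "r2"], 1 - s12 / min(s11, s22))

  expect_error(pairwise_distance(c(a = "", b = "MKL")), "empty")
  expect_error(pairwise_distance(c(a = "MKL")), "at least two")
})

test_that("neighbor joining reproduces an additive 4-taxon matrix", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(D)
  # path lengths reproduce the matrix exactly (additivity)
  expect_equal(ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-9)
  # split AB|CD with the original branch lengths
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(phangorn::RF.dist(ape::unroot(truth), tree), 0)
  bl <- setNames(
    tree$edge.length[match(seq_along(tree$tip.label), tree$edge[, 2])],
    tree$tip.label
  )
  expect_equal(bl, c(A = 1, B = 2, C = 3, D = 4))
})

test_that("three taxa resolve by the closed-form star formulas", {
  D <- matrix(c(0, 2, 3,
                2, 0, 5,
                3, 5, 0), 3, 3, dimnames = list(c("x", "y", "z"),
                                                c("x", "y", "z")))
  tree <- neighbor_joining(D)
  bl <- setNames(
    tree$edge.length[match(seq_along(tree$tip.label), tree$edge[, 2])],
    tree$tip.label
  )
  expect_equal(bl[["x"]], (2 + 3 - 5) / 2)
  expect_equal(bl[["y"]], (2 + 5 - 3) / 2)
  expect_equal(bl[["z"]], (3 + 5 - 2) / 2)
})

test_that("random additive trees are recovered at RF distance zero", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.2, 1.5))
    D <- ape::cophenetic.phylo(true)
    ord <- sample(rownames(D))
    est <- neighbor_joining(D[ord, ord])
    expect_equal(phangorn::RF.dist(ape::unroot(true), est), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), rownames(D)],
                 D, tolerance = 1e-9)
  }
})

test_that("degenerate or malformed distance matrices are rejected", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3), "symmetric")
  D3[1, ] <- c(0, NA, 2)
  expect_error(neighbor_joining(D3), "missing")
})

test_that("midpoint rooting halves the diameter and keeps path lengths", {
  two <- ape::read.tree(text = "(A:1,B:3);")
  rooted <- midpoint_root(two)
  bl <- setNames(
    rooted$edge.length[match(seq_along(rooted$tip.label),
                             rooted$edge[, 2])],
    rooted$tip.label
  )
  expect_equal(unname(bl[c("A", "B")]), c(2, 2))

  # symmetric quartet roots on the central edge
  quart <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  r <- midpoint_root(ape::unroot(quart))
  kids <- lapply(
    r$edge[r$edge[, 1] == ape::Ntip(r) + 1L, 2],
    function(nd) {
      if (nd <= ape::Ntip(r)) r$tip.label[nd]
      else ape::extract.clade(r, nd)$tip.label
    }
  )
  expect_true(setequal(kids[[1]], c("A", "B")) ||
                setequal(kids[[1]], c("C", "D")))

  # rerooting preserves all leaf-to-leaf path lengths
  set.seed(4)
  tr <- ape::unroot(ape::rtree(7, br = function(k) runif(k, 0.1, 2)))
  rr <- midpoint_root(tr)
  lab <- tr$tip.label
  expect_equal(ape::cophenetic.phylo(rr)[lab, lab],
               ape::cophenetic.phylo(tr)[lab, lab], tolerance = 1e-9)
})

test_that("MRCA clades behave on anchors and grow monotonically", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  expect_setequal(mrca_clade(tree, c("A", "B")), c("A", "B"))
  expect_identical(mrca_clade(tree, "C"), "C")
  expect_setequal(mrca_clade(tree, c("A", "C")), c("A", "B", "C", "D"))
  expect_error(mrca_clade(tree, c("A", "ZZ")), "not in tree")
  # monotone: adding an anchor never shrinks the clade
  set.seed(8)
  rt <- ape::rtree(10)
  tips <- rt$tip.label
  anchors <- sample(tips, 2)
  base <- mrca_clade(rt, anchors)
  for (extra in setdiff(tips, anchors)) {
    grown <- mrca_clade(rt, c(anchors, extra))
    expect_true(all(base %in% grown))
  }
})

test_that("prevalence and copy number summarize genome coverage", {
  meta <- data.frame(
    seq_id = sprintf("p%02d", 1:12),
    genome_id = c(sprintf("g%02d", 1:10), "g01", "g02"),
    class = rep(c("Alpha", "Beta"), 6),
    stringsAsFactors = FALSE
  )
  # members cover 9 of 10 genomes; g01 has 2 copies
  members <- c(sprintf("p%02d", 1:9), "p11")
  s <- prevalence_summary(members, meta)
  expect_equal(sum(s$prevalence$n_with_member), 9)
  expect_equal(
    s$copy_number$copies[s$copy_number$genome_id == "g01"], 2L
  )
  overall <- sum(s$prevalence$n_with_member) / sum(s$prevalence$n_genomes)
  expect_equal(overall, 0.9)
  expect_error(prevalence_summary("nope", meta), "missing from the metadata")
})

test_that("the clade pipeline is invariant to input sequence order", {
  fam <- simulate_protein_family(n_background = 15, clade_size = 4, seed = 6)
  out1 <- clade_pipeline(fam$sequences, fam$metadata)
  set.seed(2)
  perm <- sample(length(fam$sequences))
  out2 <- clade_pipeline(fam$sequences[perm], fam$metadata)
  expect_setequal(out1$members, out2$members)
  expect_equal(out1$distance[names(fam$sequences), names(fam$sequences)],
               out2$distance[names(fam$sequences), names(fam$sequences)])
})
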