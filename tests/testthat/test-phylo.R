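test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("AA-A", "AATA"), 0)
  expect_equal(p_distance("ANCA", "AGCT"), 1 / 3)
  expect_error(p_distance("----", "AAAA"), "comparable")
  expect_error(p_distance("AA", "AAA"), "length")
})

test_that("JC69 correction matches its closed form and domain", {
  expect_equal(jc69(0), 0)
  expect_equal(jc69(0.3), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_equal(jc69(0.3), 0.38312, tolerance = 1e-5)
  expect_error(jc69(0.75), "saturated")
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0, B = 2, C = 4))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on additive matrices from random trees", {
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      true <- ape::rtree(n)
      true$edge.length <- stats::runif(nrow(true$edge), 0.05, 0.6)
      dm <- stats::cophenetic(true)
      est <- nj_tree(dm)
      # topology identical to the generating tree
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), ape::unroot(est))), 0)
      # path-length oracle: every pairwise distance reproduced
      got <- stats::cophenetic(est)[rownames(dm), colnames(dm)]
      expect_lt(max(abs(got - dm)), 1e-9)
    }
  })
})

test_that("NJ topology is invariant under leaf permutation", {
  withr::with_seed(62, {
    true <- ape::rtree(8)
    true$edge.length <- stats::runif(nrow(true$edge), 0.05, 0.5)
    dm <- stats::cophenetic(true)
    perm <- sample(8)
  })
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)
})

test_that("NJ agrees with the reference implementation in ape", {
  withr::with_seed(63, {
    for (i in 1:5) {
      n <- sample(5:10, 1)
      dm <- as.matrix(stats::dist(matrix(stats::rnorm(n * 4), n)))
      dimnames(dm) <- list(paste0("t", 1:n), paste0("t", 1:n))
      expect_equal(as.numeric(ape::dist.topo(nj_tree(dm), ape::nj(dm))), 0)
    }
  })
})

test_that("a perfectly supported split gets bootstrap 100", {
  # two pairs of identical sequences, pairs separated at 50 fixed columns
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(rep("T", 50), collapse = "")
  pad <- paste(rep("G", 30), collapse = "")
  msa <- c(x1 = paste0(a, pad), x2 = paste0(a, pad),
           y1 = paste0(b, pad), y2 = paste0(b, pad))
  tr <- bootstrap_support(msa, n_reps = 100, seed = 3)
  bip <- tree_bipartitions(tr)
  expect_equal(nrow(bip), 1L)
  expect_equal(bip$key, canon_key(c("x1", "x2"), names(msa)))
  supp <- as.numeric(tr$node.label[bip$node - 4L])
  expect_equal(supp, 100)
})

test_that("support values live on internal edges in [0, 100]", {
  withr::with_seed(64, {
    root <- random_dna(2000)
    sim <- mutate_and_radiate(root, tree_leaves = 6,
                              per_site_mutation_rate = 0.05)
  })
  tr <- bootstrap_support(sim$leaves, n_reps = 20, seed = 9)
  lab <- tr$node.label[tr$node.label != ""]
  expect_true(all(as.numeric(lab) >= 0 & as.numeric(lab) <= 100))
  # root carries no support
  expect_equal(tr$node.label[1], "")
})

test_that("Newick serialisation round-trips topology, lengths, supports", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  txt <- write_newick(nj_tree(d))
  expect_match(txt, "^\\(.*A.*B.*C.*\\);$")

  withr::with_seed(65, {
    for (i in 1:30) {
      tr <- ape::rtree(sample(4:15, 1))
      f <- tempfile(fileext = ".nwk")
      write_newick(tr, f)
      back <- read_newick(f)
      unlink(f)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                             ape::unroot(back))), 0)
      expect_equal(sort(back$edge.length), sort(tr$edge.length),
                   tolerance = 1e-6)
    }
  })

  # supports parse back as internal node labels
  tr <- ape::read.tree(text = "((A:0.1,B:0.1)97:0.1,C:0.1,D:0.1);")
  expect_equal(tr$node.label, c("", "97"))
})

test_that("saturated pairs fall back to p-distance instead of failing", {
  msa <- c(a = strrep("A", 100), b = strrep("C", 100),
           c = paste0(strrep("A", 99), "C"),
           d = paste0(strrep("C", 99), "A"))
  dm <- msa_distances(msa, model = "jc69")
  expect_gte(attr(dm, "n_fallback"), 1L)
  expect_equal(dm["a", "b"], 1)     # raw p-distance fallback
})
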