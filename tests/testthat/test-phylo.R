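test_that("column masking applies the site-coverage rule arithmetically", {
  aln <- matrix("A", nrow = 20, ncol = 5,
                dimnames = list(paste0("t", 1:20), NULL))
  aln[1:2, 3] <- "-"   # 18/20 = 0.90 coverage
  aln[1, 5] <- "X"     # 19/20 = 0.95 coverage
  masked <- mask_low_coverage_columns(aln, 0.95)
  expect_equal(masked$kept, c(1L, 2L, 4L, 5L))
  # gap-free alignment and threshold 0 are identity operations
  clean <- matrix("A", 4, 6, dimnames = list(letters[1:4], NULL))
  expect_equal(mask_low_coverage_columns(clean, 0.95)$kept, 1:6)
  expect_equal(mask_low_coverage_columns(aln, 0)$kept, 1:5)
  all_gap <- matrix("-", 4, 3, dimnames = list(letters[1:4], NULL))
  expect_error(mask_low_coverage_columns(all_gap, 0.95), "coverage")
})

test_that("distances follow the closed-form gamma correction", {
  aln <- rbind(a = strsplit(strrep("A", 10), "")[[1]],
               b = c(rep("A", 8), "C", "G"))  # p = 0.2
  expect_equal(unname(compute_distances(aln, "p-distance")["a", "b"]), 0.2)
  d <- compute_distances(aln, "poisson-gamma", gamma_shape = 0.8)
  expect_equal(unname(d["a", "b"]), 0.8 * ((1 - 0.2)^(-1 / 0.8) - 1))
  expect_equal(unname(diag(d)), c(0, 0))
  # identical pair is 0 under every model
  same <- rbind(a = rep("A", 10), b = rep("A", 10))
  for (model in c("p-distance", "poisson-gamma", "jtt-gamma")) {
    expect_equal(unname(compute_distances(same, model)["a", "b"]), 0,
                 tolerance = 1e-6)
  }
  # monotone in p under a fixed shape
  ps <- seq(0.05, 0.6, by = 0.05)
  ds <- 0.8 * ((1 - ps)^(-1 / 0.8) - 1)
  expect_true(all(diff(ds) > 0))
})

test_that("the JTT-gamma model yields a symmetric zero-diagonal matrix", {
  set.seed(41)
  aa <- setdiff(rownames(substitution_matrix()),
                c("X", "*", "B", "Z", "J", "U", "O"))
  aln <- matrix(sample(aa, 5 * 60, TRUE), 5,
                dimnames = list(paste0("t", 1:5), NULL))
  d <- compute_distances(aln, "jtt-gamma", gamma_shape = 0.8)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("3-taxon NJ solves the three-point formulas exactly", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
  tree <- nj_tree(d)
  dd <- stats::cophenetic(tree)
  expect_equal(dd[rownames(d), colnames(d)], d)
  # closed-form leaf branch lengths: x = (dAB + dAC - dBC) / 2 etc.
  lens <- stats::setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                          tree$tip.label)
  expect_equal(unname(lens["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(lens["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(lens["C"]), (4 + 5 - 3) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  d_bad <- d; d_bad[1, 2] <- 10
  expect_error(nj_tree(d_bad), "symmetric")
})

test_that("NJ recovers the generating topology of additive matrices", {
  # 4-taxon case: explicit additive matrix for ((A,B),(C,D))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.4
  d["C", "D"] <- d["D", "C"] <- 0.6
  for (x in c("A", "B")) for (y in c("C", "D")) {
    d[x, y] <- d[y, x] <- 1.5
  }
  tree <- nj_tree(d)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(want)), 0,
               ignore_attr = TRUE)
  expect_true(all(tree$edge.length >= 0))
})

test_that("Newick output round-trips with supports as node labels", {
  set.seed(43)
  case <- random_additive_case(6)
  tree <- nj_tree(case$d)
  tree$node.label <- c("", "97", "88", "100")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  back <- ape::read.tree(nwk)
  expect_equal(ape::dist.topo(back, tree), 0, ignore_attr = TRUE)
  expect_true(all(c("97", "88", "100") %in% back$node.label))
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
})

test_that("bootstrap supports are reproducible and bounded", {
  set.seed(44)
  aa <- setdiff(rownames(substitution_matrix()),
                c("X", "*", "B", "Z", "J", "U", "O"))
  aln <- matrix(sample(aa, 6 * 40, TRUE), 6,
                dimnames = list(paste0("t", 1:6), NULL))
  masked <- mask_low_coverage_columns(aln, 0.95)
  t1 <- bootstrap_support(masked, model = "p-distance",
                          n_replicates = 1, seed = 7)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  t2 <- bootstrap_support(masked, model = "p-distance",
                          n_replicates = 20, seed = 7)
  t3 <- bootstrap_support(masked, model = "p-distance",
                          n_replicates = 20, seed = 7)
  expect_identical(t2$node.label, t3$node.label)
})

test_that("a planted deep split outscores shallow conflicting splits", {
  # two clades differing at many columns, plus a little within-clade noise
  set.seed(45)
  n_col <- 60
  base1 <- sample(c("A", "R", "N", "D"), n_col, TRUE)
  base2 <- base1
  flip <- sample(n_col, 30)
  base2[flip] <- sample(c("E", "G", "H", "I"), 30, TRUE)
  jitter_row <- function(base) {
    i <- sample(n_col, 2)
    base[i] <- sample(c("K", "L", "M"), 2, TRUE)
    base
  }
  aln <- rbind(a1 = jitter_row(base1), a2 = jitter_row(base1),
               a3 = jitter_row(base1), b1 = jitter_row(base2),
               b2 = jitter_row(base2), b3 = jitter_row(base2))
  masked <- mask_low_coverage_columns(aln, 0.95)
  tree <- bootstrap_support(masked, model = "p-distance",
                            n_replicates = 100, seed = 9)
  # the a|b bipartition must be in the tree and carry very strong support
  pp <- ape::prop.part(tree)
  clades <- lapply(pp, function(idx) sort(attr(pp, "labels")[idx]))
  a_side <- which(vapply(clades, function(cl)
    identical(cl, c("a1", "a2", "a3")) ||
      identical(cl, c("b1", "b2", "b3")), logical(1)))
  expect_equal(length(a_side), 1L)
  sup <- suppressWarnings(as.numeric(tree$node.label[a_side]))
  expect_gte(sup, 95)
})
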