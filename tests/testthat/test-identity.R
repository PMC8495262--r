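test_that("pairwise alignment handles the elementary cases", {
  a <- pairwise_align("ACGT", "ACGT", mode = "dna")
  expect_equal(a$aligned_a, "ACGT")
  expect_equal(a$aligned_b, "ACGT")
  expect_equal(identity_percent(a), 100)

  # one deletion: exactly one gap column
  a2 <- pairwise_align("ACGT", "AGT", mode = "dna")
  expect_equal(sum(strsplit(a2$aligned_b, "")[[1]] == "-"), 1L)
  expect_equal(nchar(a2$aligned_a), 4L)

  # single mismatch in protein mode
  a3 <- pairwise_align("MKLV", "MKIV", mode = "protein")
  expect_false(grepl("-", a3$aligned_a, fixed = TRUE))
  expect_equal(identity_percent(a3), 75)

  expect_error(pairwise_align("", "ACGT"), "empty")
})

test_that("identity respects the denominator convention", {
  a <- pairwise_align("ACGT", "ACGA", mode = "dna")
  expect_equal(identity_percent(a), 75)
  # gap columns count as mismatches under the default convention
  a2 <- pairwise_align("ACGT", "AGT", mode = "dna")
  expect_equal(identity_percent(a2, "aligned"), 75)
  expect_equal(identity_percent(a2, "nogap"), 100)
  expect_equal(identity_percent(a2, "shorter"), 100)
})

test_that("alignment and identity match the exhaustive brute-force oracle", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:7, 1)
    m <- sample(2:7, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    aln <- pairwise_align(a, b, mode = "dna")
    oracle <- brute_align_best(a, b)
    expect_equal(aln$score, oracle$score, tolerance = 1e-4,
                 info = paste(a, b))
    expect_true(any(abs(identity_percent(aln) - oracle$identities) < 1e-6),
                info = paste(a, b))
  }
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  anc <- build_ancestor(family_config(seed = 8))
  records <- rbind(anc$record, anc$record)
  records$allele_id <- c("A", "B")
  ann <- annotate_alleles(records)
  mats <- build_identity_matrices(records, ann)
  for (m in mats[c("exon_nt", "aa", "intron_nt")]) {
    expect_equal(unname(diag(m)), c(100, 100))
    expect_equal(m, t(m))
    expect_equal(unname(m["A", "B"]), 100)
  }
  expect_error(build_identity_matrices(records, ann[1]), "unannotated")
})

test_that("identity summaries track the family structure", {
  mats <- syn_matrices()
  s <- summarize_identity(mats)
  expect_equal(s$level, c("exon_nt", "aa", "intron_nt"))
  expect_true(all(s$min >= 0 & s$max <= 100))
  expect_true(all(s$mean > s$min & s$mean < s$max))
  # introns diverge faster than exons in the evolved family
  expect_lt(s$mean[s$level == "intron_nt"], s$mean[s$level == "exon_nt"])
  # wild-type/mutant amplicons are near-identical
  fam <- syn_family()
  muts <- grep("m$", fam$records$allele_id, value = TRUE)
  for (m in muts) {
    wt <- sub("m$", "", m)
    aln <- pairwise_align(
      fam$records$sequence[fam$records$allele_id == wt],
      fam$records$sequence[fam$records$allele_id == m], mode = "dna")
    expect_gt(identity_percent(aln), 97)
  }
})

test_that("trans-specific verdicts weigh identity, introns and the tree", {
  mats <- syn_matrices()
  fam <- syn_family()
  calls <- classify_trans_specific(mats, fam$records)
  expect_true(all(calls$species_a != calls$species_b))
  expect_true(all(calls$verdict %in%
                    c("supported", "ambiguous", "unsupported")))
  expect_true(all(grepl("no-tree", calls$note)))
  expect_true(all(calls$aa_identity[calls$verdict == "supported"] >= 96))
  # same-species pairs are excluded by construction
  same <- fam$records$allele_id[fam$records$species_tag == "spA"]
  expect_false(any(calls$allele_a %in% same & calls$allele_b %in% same))
})
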