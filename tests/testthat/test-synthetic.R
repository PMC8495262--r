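test_that("the generator is deterministic under a fixed seed", {
  cfg <- family_config(seed = 42, n_base_alleles = 5,
                       n_mutant_derivatives = 1, n_samples = 3,
                       trans_specific_fraction = 0.4)
  a <- simulate_family(cfg)
  b <- simulate_family(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$trans_pairs, b$truth$trans_pairs)
  expect_identical(a$truth$samples, b$truth$samples)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- emit_fixture_set(cfg, d1)
  f2 <- emit_fixture_set(cfg, d2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
})

test_that("the ancestor carries each conserved motif exactly once", {
  anc <- build_ancestor(family_config(seed = 3))
  lib <- default_motif_library()
  for (m in lib$motifs) {
    expect_equal(length(gregexpr(m, anc$protein, fixed = TRUE)[[1]]), 1L)
  }
  expect_false(grepl("*", anc$protein, fixed = TRUE))
  expect_equal(nchar(anc$record$sequence),
               3L * nchar(anc$protein) + intron_length(anc$structure))
  # splice sites are canonical by construction
  expect_equal(anc$structure$splice5_dinucleotide, "GT")
  expect_equal(anc$structure$splice3_dinucleotide, "AG")
})

test_that("a degenerate intron length range is honored exactly", {
  cfg <- family_config(seed = 5, n_base_alleles = 3,
                       n_mutant_derivatives = 0,
                       trans_specific_fraction = 0,
                       intron_length_range = c(100, 100))
  fam <- simulate_family(cfg)
  widths <- vapply(fam$truth$alleles, function(a)
    a$structure$intron2[2] - a$structure$intron2[1], integer(1))
  expect_true(all(widths == 100L))
})

test_that("amplicon and protein dimensions match the study conditions", {
  fam <- syn_family()
  lens <- nchar(fam$records$sequence)
  expect_true(all(lens >= 400 & lens <= 1600))
  base <- paste0("S", 1:20)
  intr <- vapply(fam$truth$alleles[base], function(a)
    a$structure$intron2[2] - a$structure$intron2[1], integer(1))
  expect_true(all(intr >= 81 & intr <= 1116))
  prots <- vapply(fam$truth$alleles[base], function(a)
    nchar(a$protein), integer(1))
  expect_true(all(prots >= 134 & prots <= 155))
})

test_that("trans_specific_fraction 0 yields no planted pairs", {
  cfg <- family_config(seed = 9, n_base_alleles = 4,
                       n_mutant_derivatives = 0,
                       trans_specific_fraction = 0)
  fam <- simulate_family(cfg)
  expect_equal(nrow(fam$truth$trans_pairs), 0L)
  expect_true(all(fam$records$species_tag == "spA"))
})

test_that("planted trans-specific pairs stay within 4 percent divergence", {
  fam <- syn_family()
  tp <- fam$truth$trans_pairs
  expect_gt(nrow(tp), 0L)
  expect_true(all(tp$aa_divergence <= 0.04))
  for (k in seq_len(nrow(tp))) {
    sp <- fam$records$species_tag[match(c(tp$allele_a[k], tp$allele_b[k]),
                                        fam$records$allele_id)]
    expect_equal(length(unique(sp)), 2L)
  }
})

test_that("plant_lof produces exactly the described lesions", {
  fam <- syn_family()
  t1 <- fam$truth$alleles[["S1"]]
  allele <- list(sequence = fam$records$sequence[
                   fam$records$allele_id == "S1"],
                 structure = t1$structure, protein = t1$protein)

  sp <- plant_lof(allele, "splice3-AG-to-GG")
  intron <- substr(sp$sequence, sp$structure$intron2[1] + 1L,
                   sp$structure$intron2[2])
  expect_equal(substr(intron, nchar(intron) - 1L, nchar(intron)), "GG")
  # exactly one base differs
  expect_equal(nchar(sp$sequence), nchar(allele$sequence))
  diff <- sum(strsplit(sp$sequence, "")[[1]] !=
                strsplit(allele$sequence, "")[[1]])
  expect_equal(diff, 1L)

  fs5 <- plant_lof(allele, "frameshift-upstream-C5")
  expect_equal(nchar(fs5$sequence), nchar(allele$sequence) - 1L)
  prot <- translate_cds(fs5$sequence, fs5$structure)
  expect_true(is.na(prot$stop_position))  # reads through, garbled C5

  fs2 <- plant_lof(allele, "frameshift-after-C2")
  prot2 <- translate_cds(fs2$sequence, fs2$structure)
  expect_lt(nchar(prot2$residues), 40L)

  expect_error(plant_lof(allele, "frameshift-upstream-C5", position = 0),
               "outside")
})

test_that("sample multisets explain band undercounting", {
  fam <- syn_family()
  for (sm in fam$truth$samples) {
    expect_lte(length(sm$band_representatives), length(sm$distinct))
  }
  # at ploidy 1 every sample shows exactly one band
  cfg1 <- family_config(seed = 11, n_base_alleles = 5,
                        n_mutant_derivatives = 0,
                        trans_specific_fraction = 0, ploidy = 1,
                        n_samples = 4)
  fam1 <- simulate_family(cfg1)
  for (sm in fam1$truth$samples) {
    expect_equal(length(sm$alleles), 1L)
    expect_equal(length(sm$band_representatives), 1L)
  }
})
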