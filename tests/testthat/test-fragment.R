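test_that("amplicon_length checks span arithmetic against the sequence", {
  seq <- strrep("A", 505)
  gs <- gene_structure(c(0, 100), c(100, 181), c(181, 505))
  expect_equal(amplicon_length(seq, gs), 505L)
  expect_error(amplicon_length(strrep("A", 500), gs), "cover")
  fam <- syn_family()
  id <- "S1"
  expect_equal(amplicon_length(fam$records$sequence[
                 fam$records$allele_id == id],
                 fam$truth$alleles[[id]]$structure),
               nchar(fam$records$sequence[fam$records$allele_id == id]))
})

test_that("band grouping is single-linkage and flags co-migration", {
  g <- group_bands(c(1232, 1232), 60, allele_ids = c("S17", "S18"))
  expect_equal(length(g), 1L)
  expect_true(g[[1]]$is_complex)
  expect_equal(g[[1]]$representative, 1232L)

  g2 <- group_bands(c(505, 1544), 60)
  expect_equal(length(g2), 2L)

  # chained group: no pair of adjacent gaps reaches the resolution
  g3 <- group_bands(c(500, 550, 600), 60)
  expect_equal(length(g3), 1L)
  expect_equal(g3[[1]]$members, c(500, 550, 600))

  expect_equal(length(group_bands(numeric(0), 60)), 0L)
  expect_error(group_bands(c(-5, 10), 60), "positive")
})

test_that("band grouping matches a brute-force connected-components oracle", {
  set.seed(20)
  for (rep in 1:25) {
    sizes <- sample(400:1600, sample(2:12, 1), replace = TRUE)
    res <- sample(c(1, 10, 60, 200), 1)
    got <- lapply(group_bands(sizes, res), `[[`, "members")
    want <- brute_single_linkage(sizes, res)
    expect_equal(got[order(vapply(got, min, numeric(1)))],
                 want[order(vapply(want, min, numeric(1)))])
  }
})

test_that("band grouping is permutation-invariant and resolution-monotone", {
  set.seed(21)
  sizes <- sample(400:1600, 10)
  g <- group_bands(sizes, 60)
  g_perm <- group_bands(rev(sizes), 60)
  expect_equal(lapply(g, `[[`, "members"), lapply(g_perm, `[[`, "members"))
  counts <- vapply(c(0, 1, 30, 60, 120, 500),
                   function(r) length(group_bands(sizes, r)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # resolution 0: every distinct size is its own band
  expect_equal(length(group_bands(sizes, 0)), length(unique(sizes)))
})

test_that("capillary size categories keep 1-bp neighbors distinct", {
  counts <- bin_size_categories(c(300, 301, 300))
  expect_equal(counts, stats::setNames(c(2L, 1L), c("300", "301")))
  expect_equal(length(bin_size_categories(integer(0))), 0L)

  fam <- syn_family()
  obs <- do.call(rbind, lapply(names(fam$truth$samples), function(sid) {
    data.frame(sample_id = sid,
               fragment_size = fam$truth$samples[[sid]]$first_intron_sizes,
               assay = "first-intron-capillary")
  }))
  cats <- bin_size_categories(obs)
  expect_equal(sum(cats), nrow(obs))
  expect_equal(length(cats), length(unique(obs$fragment_size)))
})

test_that("detection summaries quantify undercounting from co-migration", {
  fam <- syn_family()
  bands <- do.call(rbind, lapply(names(fam$truth$samples), function(sid) {
    reps <- fam$truth$samples[[sid]]$band_representatives
    data.frame(sample_id = sid, fragment_size = reps,
               stringsAsFactors = FALSE)
  }))
  det <- summarize_detection(fam$truth, bands)
  expect_true(all(det$undercount >= 0))
  expect_equal(det$alleles_carried - det$bands_seen, det$undercount)
  # brute-force check of one sample: bands from planted sizes
  sid <- det$sample_id[1]
  sm <- fam$truth$samples[[sid]]
  sizes <- nchar(fam$records$sequence[match(sm$amplified,
                                            fam$records$allele_id)])
  expect_equal(det$bands_seen[det$sample_id == sid],
               length(brute_single_linkage(sizes, 60)))
  expect_error(summarize_detection(fam$truth, data.frame(
    sample_id = "nope", fragment_size = 500)), "unknown sample")
})
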