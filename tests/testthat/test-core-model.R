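test_that("gene structures enforce contiguous non-empty spans", {
  gs <- gene_structure(c(0, 90), c(90, 190), c(190, 400))
  expect_equal(intron_length(gs), 100L)
  expect_error(gene_structure(c(0, 90), c(90, 90), c(90, 400)),
               "non-empty")
  expect_error(gene_structure(c(0, 90), c(91, 190), c(190, 400)),
               "contiguous")
  expect_error(gene_structure(c(0, 90), c(90, 190), c(190, 400),
                              frame_offset = 3), "frame_offset")
  # spans must cover the sequence when one is supplied
  expect_error(gene_structure(c(0, 2), c(2, 4), c(4, 9),
                              sequence = "ACGTACGT"), "cover")
})

test_that("translation follows the standard code, stops and ambiguity", {
  expect_equal(translate_dna("ATGGCTTAA"), "MA*")
  expect_equal(translate_dna("ATGGCTTAA", offset = 1), "WL")  # TGG CTT
  expect_equal(translate_dna("ATGNNNGCT"), "MXA")
  expect_equal(translate_dna("AT"), "")

  # stop codon at codon k truncates the deduced protein to k residues
  seq <- paste0("ATGGCT", "GTTTTTTTAG", "GCTTAAGCT")
  gs <- gene_structure(c(0, 6), c(6, 16), c(16, 25), sequence = seq)
  prot <- translate_cds(seq, gs)
  expect_equal(prot$residues, "MAA")
  expect_equal(prot$stop_position, 3L)
  expect_equal(splice_cds(seq, gs), "ATGGCTGCTTAAGCT")
})

test_that("region maps partition the protein with ordered spans", {
  anc <- build_ancestor(family_config(seed = 7))
  map <- locate_conserved_regions(anc$protein)
  expect_false(any(is.na(map$labels)))
  # spans ordered and non-overlapping
  spans <- Filter(Negate(is.null), map$spans)
  starts <- vapply(spans, `[`, numeric(1), 1)
  ends <- vapply(spans, `[`, numeric(1), 2)
  expect_true(all(diff(starts) > 0))
  expect_true(all(ends > starts))
  # every motif present exactly once, at the planted coordinates
  expect_equal(map$spans$C2, c(0L, 10L))
  expect_equal(map$spans$RHV, c(22L, 34L))
  expect_equal(map$spans$C5, c(134L, 144L))
  expect_equal(unname(region_of(map, c(0, 15, 25, 100))),
               c("C2", "C2-RHV", "RHV", "RC4-C5"))
  expect_equal(missing_regions(map), character(0))
})

test_that("truncated proteins lose downstream regions but keep C2", {
  anc <- build_ancestor(family_config(seed = 7))
  short <- substr(anc$protein, 1, 30)  # ends inside the RHV
  map <- locate_conserved_regions(short)
  expect_setequal(missing_regions(map), c("RHV", "C3", "RC4", "C5"))
  expect_false(any(is.na(map$labels)))
  # a protein with no C2 at all is unannotatable
  expect_error(locate_conserved_regions(strrep("A", 60)), "C2")
})

test_that("motif libraries load from YAML with validation", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("threshold: 0.7", "rhv_offset: 10"), yml)
  lib <- load_motif_library(yml)
  expect_equal(lib$threshold, 0.7)
  expect_equal(lib$rhv_offset, 10)
  expect_equal(lib$motifs, default_motif_library()$motifs)
  writeLines("bogus_key: 1", yml)
  expect_error(load_motif_library(yml), "bogus_key")
  writeLines("threshold: 1.5", yml)
  expect_error(load_motif_library(yml), "threshold")
})
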