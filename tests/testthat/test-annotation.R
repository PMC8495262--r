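test_that("intron detection recovers the planted structure exactly", {
  anc <- build_ancestor(family_config(seed = 2))
  gs <- detect_intron(anc$record$sequence)
  expect_equal(gs$intron2, anc$structure$intron2)
  expect_equal(gs$frame_offset, 0L)
  expect_equal(gs$splice5_dinucleotide, "GT")
  expect_equal(gs$splice3_dinucleotide, "AG")
})

test_that("sequences without a C2-bearing frame or donor are unannotatable", {
  expect_error(detect_intron(strrep("AC", 300)), "unannotatable")
})

test_that("splice assessment flags defects and translates retained introns", {
  # canonical sites: both flags true, no retained translation
  seq <- paste0("ATGGCT", "GTTTTTTTAG", "GCTGCTGCT")
  gs <- gene_structure(c(0, 6), c(6, 16), c(16, 25), sequence = seq)
  sa <- assess_splice_sites(seq, gs)
  expect_true(sa$donor_ok)
  expect_true(sa$acceptor_ok)
  expect_null(sa$retained_intron_translation)

  # toy gene with defective acceptor: hand-translated retained product
  # ATGG + GTAAATAAGG + CC -> ATG GGT AAA TAA ... = M G K stop
  seq2 <- paste0("ATGG", "GTAAATAAGG", "CCGCTGCTGCTGCTGCTGCTGCT")
  gs2 <- gene_structure(c(0, 4), c(4, 14), c(14, nchar(seq2)),
                        sequence = seq2)
  sa2 <- assess_splice_sites(seq2, gs2)
  expect_false(sa2$acceptor_ok)
  expect_equal(sa2$acceptor_dinucleotide, "GG")
  rt <- sa2$retained_intron_translation
  expect_equal(rt$residues, "MGK")      # terminates at the in-frame TAA
  expect_equal(rt$novel_tail_length, 2L) # beyond the exon2-encoded M
})

test_that("structure transfer maps boundaries through an alignment", {
  anc <- build_ancestor(family_config(seed = 4))
  seq <- anc$record$sequence
  # delete one base early in exon 2 -> boundaries shift by one
  mut <- paste0(substr(seq, 1, 40), substr(seq, 42, nchar(seq)))
  gs <- transfer_structure(mut, seq, anc$structure)
  expect_equal(gs$intron2, anc$structure$intron2 - 1L)
  expect_equal(gs$exon3[2], nchar(mut))
})

test_that("synonymous/nonsynonymous counting uses pathway averaging", {
  intron <- "GTTTTTTTAG"
  make <- function(exon3) {
    paste0("ATGGCT", intron, exon3)
  }
  gs <- gene_structure(c(0, 6), c(6, 16), c(16, 22))
  # identical sequences
  expect_equal(count_syn_nonsyn(make("GGAACC"), make("GGAACC"), gs),
               list(synonymous = 0, nonsynonymous = 0, indels = 0L,
                    fractional = FALSE))
  # GGA -> GGG: both glycine
  r <- count_syn_nonsyn(make("GGAACC"), make("GGGACC"), gs)
  expect_equal(r$synonymous, 1)
  expect_equal(r$nonsynonymous, 0)
  # GAA -> GTT: two orderings, hand-enumerated:
  #  E->V (nonsyn) then V->V (syn);  E->D (nonsyn) then D->V (nonsyn)
  r2 <- count_syn_nonsyn(make("GAAACC"), make("GTTACC"), gs)
  expect_equal(r2$synonymous, 0.5)
  expect_equal(r2$nonsynonymous, 1.5)
  expect_true(r2$fractional)
})

test_that("a silent wild-type/mutant pair shows only synonymous changes", {
  anc <- build_ancestor(family_config(seed = 6))
  seq <- anc$record$sequence
  choices <- c(GCT = "GCC", CGT = "CGC", GGA = "GGG")
  # plant three synonymous third-position changes in exon 3
  mut <- seq
  planted <- 0L
  pos <- anc$structure$exon3[1]
  while (planted < 3L && pos + 3L <= nchar(mut)) {
    codon_start <- pos + (3L - (pos - intron_length(anc$structure)) %% 3L) %% 3L
    codon <- substr(mut, codon_start + 1L, codon_start + 3L)
    if (codon %in% names(choices)) {
      substr(mut, codon_start + 1L, codon_start + 3L) <- choices[[codon]]
      planted <- planted + 1L
    }
    pos <- codon_start + 3L
  }
  expect_equal(planted, 3L)
  r <- count_syn_nonsyn(seq, mut, anc$structure)
  expect_equal(r$synonymous, 3)
  expect_equal(r$nonsynonymous, 0)
  expect_equal(r$indels, 0L)
})

test_that("functional calling follows the documented precedence", {
  fam <- syn_family()
  ann <- syn_annotations()
  tab <- as.data.frame(ann)
  # wild-type alleles are putative-functional with no missing regions
  base <- tab[tab$allele_id %in% paste0("S", 1:20), ]
  expect_true(all(base$status == "putative-functional"))
  expect_true(all(base$missing_regions == ""))
  # each planted class maps to its expected verdict (checked in depth in
  # the acceptance suite; here: evidence strings name the lesion)
  for (id in names(fam$truth$alleles)) {
    lof <- fam$truth$alleles[[id]]$lof
    if (is.null(lof)) next
    expect_equal(ann[[id]]$call$status, lof$expected_status, info = id)
    expect_gt(length(ann[[id]]$call$evidence), 0L)
  }
})

test_that("the splice-defect mutant reports cryptic acceptor candidates", {
  fam <- syn_family()
  ann <- syn_annotations()
  splice_id <- names(Filter(function(a) !is.null(a$lof) &&
                              a$lof$type == "splice3-AG-to-GG",
                            fam$truth$alleles))
  sa <- ann[[splice_id]]$splice
  expect_false(sa$acceptor_ok)
  expect_true(is.numeric(sa$cryptic_acceptors))
  expect_false(is.null(sa$retained_intron_translation))
})

test_that("annotation summaries and GFF3 output are well-formed", {
  ann <- syn_annotations()
  tab <- as.data.frame(ann)
  expect_equal(tab$amplicon_bp, tab$exon2_bp + tab$intron2_bp + tab$exon3_bp)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff(ann, gff)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  expect_equal(length(lines), 1L + 3L * length(ann))
  fields <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(fields) == 9L))
})
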