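test_that("replacement conservativeness follows the PAM score sign", {
  expect_equal(classify_replacement("L", "I"), "conservative")
  expect_equal(classify_replacement("G", "W"), "non-conservative")
  expect_error(classify_replacement("A", "A"), "identical")
  expect_warning(na <- classify_replacement("X", "L"), "non-standard")
  expect_true(is.na(na))
  # symmetry over random residue pairs
  set.seed(5)
  aa <- setdiff(rownames(substitution_matrix("PAM250")),
                c("X", "*", "B", "Z", "J", "U", "O"))
  for (k in 1:25) {
    pr <- sample(aa, 2)
    expect_equal(classify_replacement(pr[1], pr[2]),
                 classify_replacement(pr[2], pr[1]))
  }
})

test_that("event enumeration labels substitutions and collapses gap runs", {
  anc <- build_ancestor(family_config(seed = 12))
  map <- locate_conserved_regions(anc$protein)
  expect_equal(nrow(enumerate_substitutions(anc$protein, anc$protein,
                                            map)), 0L)
  # single substitution inside the RC4-C5 segment
  p2 <- anc$protein
  pos <- 100L  # 0-based, inside RC4-C5
  old <- substr(p2, pos + 1L, pos + 1L)
  new <- if (old == "A") "V" else "A"
  substr(p2, pos + 1L, pos + 1L) <- new
  ev <- enumerate_substitutions(anc$protein, p2, map)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "substitution")
  expect_equal(ev$region, "RC4-C5")
  expect_equal(ev$ref_position, pos)

  # a 3-residue deletion collapses to one indel event; cross-check the
  # run collapse against brute-force run-length encoding
  p3 <- paste0(substr(anc$protein, 1, 100), substr(anc$protein, 104, 144))
  ev3 <- enumerate_substitutions(anc$protein, p3, map)
  indels <- ev3[ev3$event_type == "indel", ]
  expect_equal(nrow(indels), 1L)
  expect_equal(nchar(indels$residue_a), 3L)
  aln <- pairwise_align(anc$protein, p3, mode = "protein")
  gaps <- strsplit(aln$aligned_b, "")[[1]] == "-" |
    strsplit(aln$aligned_a, "")[[1]] == "-"
  expect_equal(nrow(indels), sum(rle(gaps)$values))
})

test_that("region frequency tables conserve counts and shares", {
  anc <- build_ancestor(family_config(seed = 13))
  map <- locate_conserved_regions(anc$protein)
  set.seed(13)
  p2 <- strsplit(anc$protein, "")[[1]]
  hit <- sample(15:130, 30)
  for (i in hit) p2[i] <- sample(setdiff(LETTERS[LETTERS %in%
    rownames(substitution_matrix())], p2[i]), 1)
  ev <- enumerate_substitutions(anc$protein, paste(p2, collapse = ""), map)
  prof <- region_frequency_table(ev)
  expect_equal(sum(prof$substitutions),
               sum(ev$event_type == "substitution"))
  expect_equal(sum(prof$share_pct), 100, tolerance = 1e-9)
  expect_true(all(prof$non_conservative <= prof$substitutions))
  expect_error(region_frequency_table(ev[0, ]), "no events")

  # all events in one region -> that region takes 100 percent
  one <- ev[ev$region == ev$region[1], ]
  prof1 <- region_frequency_table(one)
  expect_equal(prof1$share_pct[prof1$region == ev$region[1]], 100)
})

test_that("pair selection honors the identity floor and mutant pairs", {
  mats <- syn_matrices()
  fam <- syn_family()
  n <- nrow(fam$records)
  all_pairs <- select_pairs(fam$records, mats, aa_floor = 0)
  expect_equal(nrow(all_pairs), n * (n - 1) / 2)
  only_mut <- select_pairs(fam$records, mats, aa_floor = 101)
  muts <- grep("m$", fam$records$allele_id, value = TRUE)
  expect_equal(nrow(only_mut), length(muts))
  expect_setequal(only_mut$allele_b, muts)
  # explicit roster overrides
  roster <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("allele_a\tallele_b", "S1\tS2"), roster)
  expect_equal(nrow(select_pairs(fam$records, mats, pairs_file = roster)),
               1L)
})

test_that("the profile is invariant to the order of pairs", {
  ann <- syn_annotations()
  pairs <- data.frame(allele_a = c("S1", "S3", "S5"),
                      allele_b = c("S2", "S4", "S6"))
  a <- mutation_region_profile(pairs, ann)
  b <- mutation_region_profile(pairs[3:1, ], ann)
  expect_equal(a$profile, b$profile)
})
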