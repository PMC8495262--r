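# Synthetic S-RNase allele family generator with a complete truth table.
#
# The generator emulates the salient features of a polyploid Prunus
# S-RNase amplicon study: ~20 divergent functional alleles plus mutant
# derivatives; amplicons spanning C2..C5 whose length variation is
# dominated by the second intron (~81-1116 bp); deduced proteins in the
# 134-155 residue band; three planted loss-of-function classes
# (frameshift just upstream of C5, frameshift after C2 creating a
# premature stop, A-to-G at the intron's penultimate 3' position);
# cross-species trans-specific allele pairs at <= 4 % amino-acid
# divergence; and multi-allele samples whose fragments co-migrate on a
# gel of limited resolution.

# Fixed protein layout of the synthetic locus (0-based half-open spans).
.SYN_LAYOUT <- list(
  C2 = c(0L, 10L), `C2-RHV` = c(10L, 22L), RHV = c(22L, 34L),
  `RHV-C3` = c(34L, 44L), C3 = c(44L, 56L), `C3-RC4` = c(56L, 70L),
  RC4 = c(70L, 80L), `RC4-C5` = c(80L, 134L), C5 = c(134L, 144L)
)
.SYN_PROT_LEN <- 144L
.SYN_EXON2_CODONS <- 30L  # intron inserted after this codon (inside RHV)
.SYN_INTRON_HEAD <- "GTAAGT"
# Pyrimidine-rich acceptor tail: the only AG (and the only G) is terminal,
# and the penultimate A is the base toggled by the splice-defect class.
.SYN_INTRON_TAIL <- "TCTTCCTTTCTTCCTTTCAG"

# Segments where replacement mutations are placed (C2 and C5 themselves
# are left untouched: the analysis of the real locus covers C2..C5 only
# partially at the termini).
.SYN_MUTABLE <- .SYN_LAYOUT[c("C2-RHV", "RHV", "RHV-C3", "C3", "C3-RC4",
                              "RC4", "RC4-C5")]

# Reverse genetic code: amino acid -> codons (stops excluded).
.codon_choices <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      by_aa <- split(names(gc), unname(gc))
      tab <<- by_aa[setdiff(names(by_aa), "*")]
    }
    tab
  }
})

#' Configuration of a synthetic allele family
#'
#' Collects every knob of the generator with defaults mirroring the study
#' conditions the package targets: 20 base alleles plus 3 mutant
#' derivatives, second-intron lengths spanning 81-1116 bp, deduced
#' proteins within 134-155 residues, region-specific replacement weights
#' concentrating mutations between RC4 and C5, and a docosaploid-like
#' sampling design (22 allele copies per sample).
#'
#' @param n_base_alleles Number of functional base alleles.
#' @param n_mutant_derivatives Number of loss-of-function derivatives
#'   (cycling through the three planted classes).
#' @param intron_length_range Second-intron length bounds (bp).
#' @param protein_length_range Deduced-protein length bounds (residues);
#'   the generator uses the rounded midpoint.
#' @param region_rate_weights Named non-negative relative substitution
#'   rates for the seven mutable segments.
#' @param species_labels Two species tags; base alleles carry the first,
#'   trans-specific duplicates the second.
#' @param trans_specific_fraction Fraction of base alleles duplicated into
#'   the second species with at most 4 percent further amino-acid
#'   divergence.
#' @param divergence_range Per-allele amino-acid divergence from the
#'   ancestor (fraction of mutable residues).
#' @param trans_divergence_range Extra divergence of a trans-specific
#'   duplicate from its parent (kept well under 0.04).
#' @param intron_subst_rate Per-base substitution rate applied to each
#'   allele's intron core.
#' @param pair_intron_rate Neutral intron noise rate for mutant
#'   derivatives and trans-specific duplicates.
#' @param ploidy Allele copies drawn per simulated sample.
#' @param n_samples Number of simulated samples.
#' @param gel_resolution_bp Gel resolution used when emitting fragment
#'   observations.
#' @param dropout_prob Per-allele amplification dropout probability.
#' @param seed RNG seed; a fixed seed makes every output byte-identical.
#' @return A validated list of class `family_config`.
#' @export
family_config <- function(n_base_alleles = 20L, n_mutant_derivatives = 3L,
                          intron_length_range = c(81L, 1116L),
                          protein_length_range = c(134L, 155L),
                          region_rate_weights = c(
                            `C2-RHV` = 8, RHV = 16, `RHV-C3` = 8, C3 = 3,
                            `C3-RC4` = 17, RC4 = 5, `RC4-C5` = 43),
                          species_labels = c("spA", "spB"),
                          trans_specific_fraction = 0.6,
                          divergence_range = c(0.05, 0.30),
                          trans_divergence_range = c(0.005, 0.035),
                          intron_subst_rate = 0.15,
                          pair_intron_rate = 0.005,
                          ploidy = 22L, n_samples = 10L,
                          gel_resolution_bp = 60, dropout_prob = 0,
                          seed = 1L) {
  cfg <- list(n_base_alleles = as.integer(n_base_alleles),
              n_mutant_derivatives = as.integer(n_mutant_derivatives),
              intron_length_range = as.integer(intron_length_range),
              protein_length_range = as.integer(protein_length_range),
              region_rate_weights = region_rate_weights,
              species_labels = species_labels,
              trans_specific_fraction = trans_specific_fraction,
              divergence_range = divergence_range,
              trans_divergence_range = trans_divergence_range,
              intron_subst_rate = intron_subst_rate,
              pair_intron_rate = pair_intron_rate,
              ploidy = as.integer(ploidy),
              n_samples = as.integer(n_samples),
              gel_resolution_bp = gel_resolution_bp,
              dropout_prob = dropout_prob,
              seed = as.integer(seed))
  if (cfg$n_base_alleles < 1L) stop("n_base_alleles must be >= 1")
  if (diff(cfg$intron_length_range) < 0 ||
      cfg$intron_length_range[1] < nchar(.SYN_INTRON_HEAD) +
        nchar(.SYN_INTRON_TAIL)) {
    stop("intron_length_range is infeasible (minimum ",
         nchar(.SYN_INTRON_HEAD) + nchar(.SYN_INTRON_TAIL), " bp)")
  }
  if (diff(cfg$protein_length_range) < 0) {
    stop("protein_length_range must be non-degenerate")
  }
  target <- round(mean(cfg$protein_length_range))
  if (target < .SYN_PROT_LEN || cfg$protein_length_range[1] > .SYN_PROT_LEN ||
      cfg$protein_length_range[2] < .SYN_PROT_LEN) {
    # the fixed layout must fit the requested band
    if (cfg$protein_length_range[1] > .SYN_PROT_LEN ||
        cfg$protein_length_range[2] < .SYN_PROT_LEN) {
      stop("protein_length_range must contain ", .SYN_PROT_LEN,
           " residues (the generator's fixed layout)")
    }
  }
  w <- cfg$region_rate_weights
  if (is.null(names(w)) || !setequal(names(w), names(.SYN_MUTABLE))) {
    stop("region_rate_weights must be named: ",
         paste(names(.SYN_MUTABLE), collapse = ", "))
  }
  if (any(w < 0) || sum(w) == 0) {
    stop("region_rate_weights must be non-negative and not all zero")
  }
  if (cfg$trans_specific_fraction < 0 || cfg$trans_specific_fraction > 1) {
    stop("trans_specific_fraction must be in [0, 1]")
  }
  if (length(cfg$species_labels) < 2L &&
      cfg$trans_specific_fraction > 0) {
    stop("two species labels are required for trans-specific pairs")
  }
  structure(cfg, class = "family_config")
}

# Analytic region map of the synthetic layout (identical in shape to
# locate_conserved_regions() output).
.syn_region_map <- function() {
  labels <- character(.SYN_PROT_LEN)
  for (nm in names(.SYN_LAYOUT)) {
    s <- .SYN_LAYOUT[[nm]]
    labels[(s[1] + 1L):s[2]] <- nm
  }
  spans <- .SYN_LAYOUT[c("C2", "RHV", "C3", "RC4", "C5")]
  structure(list(spans = spans, labels = labels,
                 protein_length = .SYN_PROT_LEN, placements = NULL),
            class = "region_map")
}

.random_intron_core <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.substitute_dna <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Build an intron of exactly `target_len` bp derived from `core_source`.
.derive_intron <- function(core_source, target_len, subst_rate) {
  head <- .SYN_INTRON_HEAD
  tail <- .SYN_INTRON_TAIL
  core_len <- target_len - nchar(head) - nchar(tail)
  core <- core_source
  # a couple of neutral indels, geometric lengths with mean 4 bp
  n_indel <- stats::rpois(1L, 2L)
  for (k in seq_len(n_indel)) {
    len <- stats::rgeom(1L, 0.25) + 1L
    if (nchar(core) < len + 2L) break
    at <- sample.int(nchar(core) - len, 1L)
    if (stats::runif(1) < 0.5) {
      core <- paste0(substr(core, 1L, at), substr(core, at + len + 1L,
                                                  nchar(core)))
    } else {
      core <- paste0(substr(core, 1L, at), .random_intron_core(len),
                     substr(core, at + 1L, nchar(core)))
    }
  }
  if (nchar(core) > core_len) {
    core <- substr(core, 1L, core_len)
  } else if (nchar(core) < core_len) {
    core <- paste0(core, .random_intron_core(core_len - nchar(core)))
  }
  core <- .substitute_dna(core, subst_rate)
  paste0(head, core, tail)
}

# Assemble an amplicon from a CDS and an intron; returns sequence and
# gene_structure.
.assemble_amplicon <- function(cds, intron) {
  e2 <- 3L * .SYN_EXON2_CODONS
  seq <- paste0(substr(cds, 1L, e2), intron,
                substr(cds, e2 + 1L, nchar(cds)))
  gs <- gene_structure(exon2 = c(0L, e2),
                       intron2 = c(e2, e2 + nchar(intron)),
                       exon3 = c(e2 + nchar(intron), nchar(seq)),
                       frame_offset = 0L, sequence = seq)
  list(sequence = seq, structure = gs)
}

#' Build the ancestral synthetic allele
#'
#' Constructs the ancestor every family member is evolved from: a
#' 144-residue protein carrying the library's C2/C3/RC4/C5 consensus
#' motifs exactly once each at the canonical spacings, with random
#' inter-motif and RHV residues; a coding sequence with codons drawn
#' uniformly among synonymous choices; and a GT..AG second intron of
#' mid-range length inserted at a fixed codon inside the RHV.
#'
#' @param config A `family_config`; its seed makes the ancestor
#'   reproducible.
#' @param library Motif library supplying the consensus motifs.
#' @return List with `record` (one-row allele table), `structure`
#'   (`gene_structure`), `region_map`, `protein` (string) and `cds`.
#' @export
build_ancestor <- function(config = family_config(),
                           library = default_motif_library()) {
  set.seed(config$seed)
  choices <- .codon_choices()
  aas <- names(choices)
  prot <- character(.SYN_PROT_LEN)
  for (nm in names(.SYN_LAYOUT)) {
    s <- .SYN_LAYOUT[[nm]]
    idx <- (s[1] + 1L):s[2]
    if (nm %in% names(library$motifs)) {
      motif <- strsplit(library$motifs[[nm]], "")[[1]]
      if (length(motif) != length(idx)) {
        stop("motif ", nm, " does not fit the generator layout (",
             length(idx), " residues)")
      }
      prot[idx] <- motif
    } else {
      prot[idx] <- sample(aas, length(idx), replace = TRUE)
    }
  }
  cds <- paste(vapply(prot, function(a) sample(choices[[a]], 1L),
                      character(1)), collapse = "")
  # Shifted-frame engineering so the planted frameshift classes behave
  # deterministically in every descendant (C2 and C5 codons are never
  # mutated by evolve_family, and the post-C2 segment retains the
  # property with high probability):
  # (a) the C5 block must read through without a stop in the +1/+2 frames,
  #     so a frameshift just upstream of C5 yields a garbled but
  #     uninterrupted tail (frameshift-truncated, not premature-stop);
  c5 <- .SYN_LAYOUT$C5
  repeat {
    block <- substr(cds, 3L * c5[1] + 1L, 3L * c5[2])
    if (!grepl("*", translate_dna(block, 1L), fixed = TRUE) &&
        !grepl("*", translate_dna(block, 2L), fixed = TRUE)) break
    for (p in seq.int(c5[1], c5[2] - 1L)) {
      substr(cds, 3L * p + 1L, 3L * p + 3L) <-
        sample(choices[[prot[p + 1L]]], 1L)
    }
  }
  # (b) the segment after C2 must carry an early stop in the +1 frame, so
  #     a frameshift there truncates the product well before the RHV end.
  seg <- .SYN_LAYOUT$`C2-RHV`
  repeat {
    t1 <- translate_dna(cds, 1L)
    if (grepl("*", substr(t1, seg[1] + 1L, .SYN_EXON2_CODONS - 1L),
              fixed = TRUE)) break
    for (p in seq.int(seg[1], seg[2] - 1L)) {
      aa <- sample(names(choices), 1L)
      prot[p + 1L] <- aa
      substr(cds, 3L * p + 1L, 3L * p + 3L) <- sample(choices[[aa]], 1L)
    }
  }
  intron_len <- round(mean(config$intron_length_range))
  core_len <- intron_len - nchar(.SYN_INTRON_HEAD) - nchar(.SYN_INTRON_TAIL)
  intron <- paste0(.SYN_INTRON_HEAD, .random_intron_core(core_len),
                   .SYN_INTRON_TAIL)
  amp <- .assemble_amplicon(cds, intron)
  record <- data.frame(allele_id = "ancestor", sequence = amp$sequence,
                       sample_id = NA_character_,
                       accession = NA_character_,
                       species_tag = config$species_labels[1],
                       stringsAsFactors = FALSE)
  list(record = record, structure = amp$structure,
       region_map = .syn_region_map(),
       protein = paste(prot, collapse = ""), cds = cds, intron = intron)
}

# Apply `n_sub` amino-acid replacements to a protein/cds pair, placed by
# the per-segment weights; returns updated protein, cds, and the 0-based
# positions hit.
.apply_region_substitutions <- function(prot_chars, cds, n_sub, weights) {
  choices <- .codon_choices()
  aas <- names(choices)
  segs <- sample(names(.SYN_MUTABLE), n_sub, replace = TRUE,
                 prob = weights[names(.SYN_MUTABLE)])
  positions <- integer(0)
  for (seg in segs) {
    s <- .SYN_MUTABLE[[seg]]
    avail <- setdiff(seq.int(s[1], s[2] - 1L), positions)
    if (length(avail) == 0L) next
    pos <- if (length(avail) == 1L) avail else sample(avail, 1L)
    positions <- c(positions, pos)
    new_aa <- sample(setdiff(aas, prot_chars[pos + 1L]), 1L)
    prot_chars[pos + 1L] <- new_aa
    codon <- sample(choices[[new_aa]], 1L)
    substr(cds, 3L * pos + 1L, 3L * pos + 3L) <- codon
  }
  list(protein = prot_chars, cds = cds, positions = sort(positions))
}

#' Evolve a family of base alleles from the ancestor
#'
#' Each base allele receives amino-acid replacements at a random overall
#' divergence (default 5-30 percent of mutable residues) placed according
#' to the per-segment rate weights, and a freshly resized, substituted and
#' indel-bearing second intron, so that exon identity stays high while
#' introns diverge faster -- the pattern seen in real S-RNase families. A
#' configurable fraction of alleles is then duplicated into the second
#' species label with at most 4 percent further amino-acid divergence and
#' near-identical introns: these are the planted trans-specific pairs.
#'
#' @param ancestor Output of [build_ancestor()].
#' @param config A `family_config`.
#' @return List with `records` (allele table: base alleles then
#'   duplicates) and `truth` (per-allele structures, substitution
#'   positions and segment labels, trans-specific pair list).
#' @export
evolve_family <- function(ancestor, config = family_config()) {
  set.seed(config$seed + 1L)
  n <- config$n_base_alleles
  n_mutable <- sum(vapply(.SYN_MUTABLE, diff, integer(1)))
  anc_prot <- strsplit(ancestor$protein, "")[[1]]
  anc_core <- substr(ancestor$intron, nchar(.SYN_INTRON_HEAD) + 1L,
                     nchar(ancestor$intron) - nchar(.SYN_INTRON_TAIL))
  alleles <- list()
  truth_alleles <- list()
  for (i in seq_len(n)) {
    id <- paste0("S", i)
    d <- stats::runif(1, config$divergence_range[1],
                      config$divergence_range[2])
    sub <- .apply_region_substitutions(anc_prot, ancestor$cds,
                                       round(d * n_mutable),
                                       config$region_rate_weights)
    target_len <- round(stats::runif(1, config$intron_length_range[1],
                                     config$intron_length_range[2]))
    intron <- .derive_intron(anc_core, target_len,
                             config$intron_subst_rate)
    amp <- .assemble_amplicon(sub$cds, intron)
    alleles[[id]] <- data.frame(
      allele_id = id, sequence = amp$sequence,
      sample_id = NA_character_, accession = NA_character_,
      species_tag = config$species_labels[1], stringsAsFactors = FALSE)
    truth_alleles[[id]] <- list(
      structure = amp$structure, parent = "ancestor",
      protein = paste(sub$protein, collapse = ""), cds = sub$cds,
      substitution_positions = sub$positions,
      substitution_segments = .syn_region_map()$labels[sub$positions + 1L],
      first_intron_bp = sample(130:330, 1L),
      lof = NULL)
  }
  # trans-specific duplicates in the second species
  trans_pairs <- data.frame(allele_a = character(), allele_b = character(),
                            aa_divergence = numeric(),
                            stringsAsFactors = FALSE)
  k <- round(config$trans_specific_fraction * n)
  if (k > 0L) {
    parents <- sort(sample(names(alleles), k))
    for (pid in parents) {
      did <- paste0(pid, "h")
      pt <- truth_alleles[[pid]]
      dd <- stats::runif(1, config$trans_divergence_range[1],
                         config$trans_divergence_range[2])
      sub <- .apply_region_substitutions(
        strsplit(pt$protein, "")[[1]], pt$cds, max(1L, round(dd * n_mutable)),
        config$region_rate_weights)
      intron <- .substitute_dna(
        span_seq(alleles[[pid]]$sequence, pt$structure$intron2),
        config$pair_intron_rate)
      # keep the terminal dinucleotides intact
      substr(intron, 1L, 2L) <- "GT"
      substr(intron, nchar(intron) - 1L, nchar(intron)) <- "AG"
      amp <- .assemble_amplicon(sub$cds, intron)
      alleles[[did]] <- data.frame(
        allele_id = did, sequence = amp$sequence,
        sample_id = NA_character_, accession = NA_character_,
        species_tag = config$species_labels[2], stringsAsFactors = FALSE)
      truth_alleles[[did]] <- list(
        structure = amp$structure, parent = pid,
        protein = paste(sub$protein, collapse = ""), cds = sub$cds,
        substitution_positions = sub$positions,
        substitution_segments =
          .syn_region_map()$labels[sub$positions + 1L],
        first_intron_bp = pt$first_intron_bp + sample(-1:1, 1L),
        lof = NULL)
      mism <- sum(strsplit(truth_alleles[[did]]$protein, "")[[1]] !=
                    strsplit(pt$protein, "")[[1]])
      trans_pairs <- rbind(trans_pairs, data.frame(
        allele_a = pid, allele_b = did,
        aa_divergence = mism / .SYN_PROT_LEN, stringsAsFactors = FALSE))
    }
  }
  records <- do.call(rbind, alleles)
  rownames(records) <- NULL
  list(records = records,
       truth = list(alleles = truth_alleles, trans_pairs = trans_pairs))
}

#' Plant a loss-of-function event in an allele
#'
#' The three planted classes mirror the lesions found in real mutated
#' S-RNases: `frameshift-upstream-C5` deletes one base just upstream of
#' the C5-coding codons of exon 3 (the frameshifted product loses C5 but
#' reaches the end of the amplicon without a new stop);
#' `frameshift-after-C2` deletes one base shortly after the C2-coding
#' codons of exon 2, creating a premature stop that truncates the protein
#' below 40 residues; `splice3-AG-to-GG` mutates the intron's penultimate
#' base from A to G, turning the canonical AG acceptor into GG.
#'
#' @param allele List with `sequence`, `structure`, `protein` (e.g. one
#'   entry of a family truth table together with its record sequence).
#' @param lof_type One of the three classes above.
#' @param position Optional explicit 0-based amplicon position of the
#'   event; must fall inside the segment targeted by `lof_type`.
#' @return List with `sequence`, `structure` (updated spans), and `lof`
#'   (list: `type`, `position`, `expected_status`, `detail`).
#' @export
plant_lof <- function(allele,
                      lof_type = c("frameshift-upstream-C5",
                                   "frameshift-after-C2",
                                   "splice3-AG-to-GG"),
                      position = NULL) {
  lof_type <- match.arg(lof_type)
  seq <- allele$sequence
  gs <- allele$structure
  intron_w <- intron_length(gs)
  # amplicon coordinate of a CDS coordinate (frame 0 layout)
  amp_of_cds <- function(p) if (p < gs$exon2[2]) p else p + intron_w

  delete_base <- function(at) { # 0-based amplicon position
    paste0(substr(seq, 1L, at), substr(seq, at + 2L, nchar(seq)))
  }

  if (lof_type == "frameshift-upstream-C5") {
    c5 <- .SYN_LAYOUT$C5
    window_cds <- seq.int(3L * (c5[1] - 8L), 3L * c5[1] - 1L)
    cand <- vapply(window_cds, amp_of_cds, numeric(1))
    if (!is.null(position)) {
      if (!position %in% cand) {
        stop("position ", position, " is outside the segment upstream of C5")
      }
      cand <- position
    }
    for (at in cand) {
      mut_seq <- delete_base(at)
      mut_gs <- gene_structure(gs$exon2, gs$intron2,
                               c(gs$exon3[1], gs$exon3[2] - 1L),
                               gs$frame_offset, mut_seq)
      prot <- translate_cds(mut_seq, mut_gs)
      if (is.na(prot$stop_position)) {
        return(list(sequence = mut_seq, structure = mut_gs,
                    lof = list(type = lof_type, position = at,
                               expected_status = "frameshift-truncated",
                               detail = sprintf(
                                 "1-nt deletion at amplicon pos %d", at))))
      }
    }
    stop("no deletion position upstream of C5 avoids a premature stop; ",
         "re-seed the family")
  }

  if (lof_type == "frameshift-after-C2") {
    win <- .SYN_LAYOUT$`C2-RHV`
    window_cds <- seq.int(3L * win[1], 3L * win[2] - 1L)
    cand <- vapply(window_cds, amp_of_cds, numeric(1))
    if (!is.null(position)) {
      if (!position %in% cand) {
        stop("position ", position, " is outside the segment after C2")
      }
      cand <- position
    }
    best <- NULL
    for (at in cand) {
      mut_seq <- delete_base(at)
      mut_gs <- gene_structure(c(0L, gs$exon2[2] - 1L),
                               gs$intron2 - 1L, gs$exon3 - 1L,
                               gs$frame_offset, mut_seq)
      prot <- translate_cds(mut_seq, mut_gs)
      sp <- prot$stop_position
      if (!is.na(sp) && sp < .SYN_LAYOUT$C5[1] &&
          (is.null(best) || sp < best$stop)) {
        best <- list(seq = mut_seq, gs = mut_gs, at = at, stop = sp)
        if (sp < 40L) break  # the canonical early-truncation outcome
      }
    }
    if (is.null(best)) {
      stop("no deletion position after C2 yields a stop upstream of C5; ",
           "re-seed the family")
    }
    return(list(sequence = best$seq, structure = best$gs,
                lof = list(type = lof_type, position = best$at,
                           expected_status = "premature-stop",
                           detail = sprintf(
                             "1-nt deletion at amplicon pos %d; stop after %d residues",
                             best$at, best$stop))))
  }

  # splice3-AG-to-GG
  at <- gs$intron2[2] - 2L # 0-based penultimate intron base
  if (!is.null(position) && position != at) {
    stop("position ", position, " is not the intron's penultimate base (",
         at, ")")
  }
  if (substr(seq, at + 1L, at + 1L) != "A") {
    stop("intron acceptor is not canonical AG; cannot plant the defect")
  }
  mut_seq <- seq
  substr(mut_seq, at + 1L, at + 1L) <- "G"
  mut_gs <- gene_structure(gs$exon2, gs$intron2, gs$exon3,
                           gs$frame_offset, mut_seq)
  list(sequence = mut_seq, structure = mut_gs,
       lof = list(type = lof_type, position = at,
                  expected_status = "splice-defect",
                  detail = sprintf(
                    "A-to-G at amplicon pos %d (intron penultimate base)",
                    at)))
}

#' Simulate a complete synthetic allele family
#'
#' Orchestrates [build_ancestor()], [evolve_family()], the planting of
#' loss-of-function derivatives via [plant_lof()] (parents drawn from the
#' base alleles, one class per derivative in rotation, with neutral intron
#' noise so that wild-type/mutant amplicon identity sits near 99
#' percent), and the drawing of per-sample allele multisets (with
#' replacement, emulating multiple genomic copies of an allele in a
#' polyploid).
#'
#' @param config A `family_config`.
#' @param library Motif library.
#' @return A list of class `family_truth` bundling `records` (full allele
#'   table), `truth` (`$ancestor`, `$alleles`, `$trans_pairs`,
#'   `$samples`), and `config`.
#' @export
simulate_family <- function(config = family_config(),
                            library = default_motif_library()) {
  anc <- build_ancestor(config, library)
  fam <- evolve_family(anc, config)
  records <- fam$records
  truth <- fam$truth
  truth$ancestor <- list(structure = anc$structure, protein = anc$protein,
                         cds = anc$cds, region_map = anc$region_map,
                         sequence = anc$record$sequence)

  set.seed(config$seed + 2L)
  lof_classes <- c("frameshift-upstream-C5", "frameshift-after-C2",
                   "splice3-AG-to-GG")
  n_mut <- config$n_mutant_derivatives
  if (n_mut > 0L) {
    base_ids <- paste0("S", seq_len(config$n_base_alleles))
    parents <- sample(base_ids, n_mut)
    for (m in seq_len(n_mut)) {
      pid <- parents[m]
      mid <- paste0(pid, "m")
      pt <- truth$alleles[[pid]]
      pseq <- records$sequence[records$allele_id == pid]
      # neutral intron noise, then the planted event
      intron <- .substitute_dna(span_seq(pseq, pt$structure$intron2),
                                config$pair_intron_rate)
      substr(intron, 1L, 2L) <- "GT"
      substr(intron, nchar(intron) - 1L, nchar(intron)) <- "AG"
      noisy <- .assemble_amplicon(pt$cds, intron)
      planted <- plant_lof(list(sequence = noisy$sequence,
                                structure = noisy$structure,
                                protein = pt$protein),
                           lof_classes[(m - 1L) %% 3L + 1L])
      records <- rbind(records, data.frame(
        allele_id = mid, sequence = planted$sequence,
        sample_id = NA_character_, accession = NA_character_,
        species_tag = config$species_labels[1], stringsAsFactors = FALSE))
      truth$alleles[[mid]] <- list(
        structure = planted$structure, parent = pid,
        protein = NA_character_, cds = NA_character_,
        substitution_positions = pt$substitution_positions,
        substitution_segments = pt$substitution_segments,
        first_intron_bp = pt$first_intron_bp,
        lof = planted$lof)
    }
  }

  # per-sample allele multisets (species-A alleles only) and observations
  set.seed(config$seed + 3L)
  pool <- records$allele_id[records$species_tag ==
                              config$species_labels[1]]
  sizes <- stats::setNames(nchar(records$sequence), records$allele_id)
  first_intron <- vapply(truth$alleles, function(a) a$first_intron_bp,
                         numeric(1))
  samples <- list()
  for (s in seq_len(config$n_samples)) {
    sid <- as.character(s)
    drawn <- sample(pool, config$ploidy, replace = TRUE)
    carried <- sort(unique(drawn))
    amplified <- carried[stats::runif(length(carried)) >=
                           config$dropout_prob]
    bands <- group_bands(unname(sizes[amplified]),
                         config$gel_resolution_bp,
                         allele_ids = amplified)
    samples[[sid]] <- list(alleles = drawn, distinct = carried,
                           amplified = amplified,
                           band_representatives = vapply(
                             bands, `[[`, integer(1), "representative"),
                           first_intron_sizes =
                             sort(unname(first_intron[amplified])))
  }
  truth$samples <- samples
  validate_alleles(records)
  structure(list(records = records, truth = truth, config = config),
            class = "family_truth")
}

#' Write a synthetic family fixture to disk
#'
#' Emits the allele FASTA, the per-sample fragment observation TSV (gel
#' bands after co-migration collapse, plus first-intron capillary sizes)
#' and the truth table as JSON. Given the same config (and seed) the
#' files are byte-identical across runs.
#'
#' @param config A `family_config`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
emit_fixture_set <- function(config = family_config(),
                             out_dir = ".") {
  fam <- simulate_family(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, "alleles.fasta")
  write_fasta(fam$records, fasta)

  rows <- list()
  for (sid in names(fam$truth$samples)) {
    sm <- fam$truth$samples[[sid]]
    for (b in sm$band_representatives) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, size_bp = b, assay = "second-intron-gel",
        stringsAsFactors = FALSE)
    }
    for (f in sm$first_intron_sizes) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, size_bp = f, assay = "first-intron-capillary",
        stringsAsFactors = FALSE)
    }
  }
  frag <- file.path(out_dir, "fragments.tsv")
  write_tsv_report(do.call(rbind, rows), frag)

  truth_json <- file.path(out_dir, "truth.json")
  serial <- list(
    config = unclass(fam$config),
    alleles = lapply(fam$truth$alleles, function(a) list(
      exon2 = a$structure$exon2, intron2 = a$structure$intron2,
      exon3 = a$structure$exon3, parent = a$parent,
      substitution_positions = a$substitution_positions,
      substitution_segments = a$substitution_segments,
      first_intron_bp = a$first_intron_bp,
      lof = a$lof)),
    trans_pairs = fam$truth$trans_pairs,
    samples = lapply(fam$truth$samples, function(sm)
      sm[c("alleles", "distinct", "band_representatives",
           "first_intron_sizes")])
  )
  jsonlite::write_json(serial, truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(fasta = fasta, fragments = frag, truth = truth_json)
}
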