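# Gene-structure detection, splice-site assessment, functional calling and
# synonymous/nonsynonymous counting.
#
# Intron detection is motif-anchored: the amplicon is assumed to start
# inside C2 (the forward primer is anchored there), so the reading frame is
# the one whose translation opens with the C2 consensus. Candidate introns
# are GT..NG intervals; the chosen one maximizes the total conserved-motif
# score of the spliced translation, with a spacing penalty against the
# library's expected inter-motif gaps so that in-frame decoy splice sites
# (which leave every motif intact but shift the spacing) are discriminated.

# Internal: per-frame full translations, reused across candidates.
.frame_translations <- function(sequence) {
  lapply(0:2, function(f) translate_dna(sequence, f))
}

# Splice-signal score of a candidate intron [g, a): donor consensus match
# (GTAAGT), polypyrimidine tract ahead of the acceptor, and a canonical-AG
# acceptor bonus. Small relative to motif scores, so it only discriminates
# between candidates whose spliced translations score identically (e.g.
# equal-length decoy intervals inside the unconstrained C2..C3 window).
.splice_signal_score <- function(chars, g, a) {
  sc <- 0
  consensus <- c("A", "A", "G", "T")  # positions 3..6 of GTAAGT
  idx <- g + 3:6
  ok <- idx <= length(chars)
  sc <- sc + 0.25 * sum(chars[idx[ok]] == consensus[ok])
  if (a >= 2L && chars[a - 1L] == "A" && chars[a] == "G") sc <- sc + 1
  tract <- chars[max(1L, a - 13L):max(1L, a - 2L)]
  sc + 0.3 * sum(tract %in% c("C", "T"))
}

#' Detect the second intron of an S-RNase amplicon
#'
#' Finds the exon2/intron2/exon3 structure of an amplicon spanning C2 to
#' C5. Donor candidates are `GT` dinucleotides; acceptor candidates are any
#' dinucleotide ending in `G` (so the canonical `AG` and defective
#' acceptors such as `GG` are both considered; non-canonical acceptors are
#' flagged by [assess_splice_sites()], not rejected here). The candidate
#' whose removal yields the best-scoring spliced translation wins.
#'
#' Candidates whose exon 2 translation runs through a stop codon, or whose
#' exon 3 translation cannot reach the end of the amplicon without a stop,
#' cannot outscore a clean candidate and are skipped; if no clean candidate
#' exists (e.g. a frameshifted pseudogene where every splicing yields the
#' same truncated product) the structure is ambiguous and an error of class
#' `srnase_ambiguous_structure` is raised listing the tied candidates --
#' use [transfer_structure()] with a close relative in that case.
#'
#' @param sequence Amplicon sequence (or a one-row allele table).
#' @param library Motif library, see [default_motif_library()].
#' @param min_intron,min_exon3 Minimum widths (bp) of the intron and of the
#'   exon 3 remainder considered during the search.
#' @return A `gene_structure` with the frame offset set.
#' @export
detect_intron <- function(sequence, library = default_motif_library(),
                          min_intron = 30L, min_exon3 = 24L) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  n <- nchar(sequence)
  mat <- substitution_matrix(library$matrix_name)
  c2 <- library$motifs[["C2"]]
  m2 <- nchar(c2)

  trans <- .frame_translations(sequence)
  seq_chars <- strsplit(sequence, "")[[1]]
  # Frames whose translation opens with C2.
  c2_idx <- .aa_encode(c2, mat)
  c2_self <- sum(diag(mat)[c2_idx])
  frames <- Filter(function(f) {
    p <- trans[[f + 1L]]
    if (nchar(p) < m2) return(FALSE)
    head_idx <- .aa_encode(substr(p, 1L, m2), mat)
    v <- mat[cbind(c2_idx, head_idx)]
    v[is.na(v)] <- 0
    sum(v) >= library$threshold * c2_self
  }, 0:2)
  if (length(frames) == 0L) {
    stop("unannotatable amplicon: no reading frame opens with the C2 motif")
  }

  # Donor candidates: GT dinucleotides (0-based start of the intron).
  donors <- gregexpr("GT", sequence, fixed = TRUE)[[1]]
  donors <- if (donors[1] == -1L) integer(0) else as.integer(donors) - 1L
  if (length(donors) == 0L) {
    stop("unannotatable amplicon: no GT splice donor present")
  }
  # Acceptor candidates: 0-based end (exclusive) of the intron; the base at
  # a-1 must be G so the acceptor dinucleotide is NG.
  gpos <- gregexpr("G", sequence, fixed = TRUE)[[1]]
  acceptors <- as.integer(gpos) # end-exclusive coordinate = G position + 1
  # First stop codon (1-based codon index, Inf if none) per frame, and last
  # stop codon, to prune candidates that cannot yield a clean translation.
  first_stop <- vapply(trans, function(p) {
    s <- regexpr("*", p, fixed = TRUE)
    if (s > 0L) as.numeric(s) else Inf
  }, numeric(1))
  last_stop <- vapply(trans, function(p) {
    s <- gregexpr("*", p, fixed = TRUE)[[1]]
    if (s[1] == -1L) 0 else as.numeric(max(s))
  }, numeric(1))

  candidates <- list()
  for (f in frames) {
    p_f <- trans[[f + 1L]]
    # exon 2 must contain C2 and translate cleanly up to the donor
    g_max_clean <- f + 3L * (min(first_stop[f + 1L], Inf) - 1L) + 2L
    ok_donors <- donors[donors >= f + 3L * m2 &
                        donors <= n - min_intron - min_exon3]
    clean_donors <- ok_donors[ok_donors <= g_max_clean]
    use_donors <- if (length(clean_donors) > 0L) clean_donors else ok_donors
    for (g in use_donors) {
      n2 <- (g - f) %/% 3L
      r <- (g - f) %% 3L
      prefix <- substr(p_f, 1L, n2)
      acc <- acceptors[acceptors >= g + min_intron & acceptors <= n - min_exon3]
      if (length(acc) == 0L) next
      for (a in acc) {
        take <- (3L - r) %% 3L
        junction <- if (r > 0L) {
          codon <- paste0(substr(sequence, g - r + 1L, g),
                          substr(sequence, a + 1L, a + take))
          aa <- .codon_table()[codon]
          if (is.na(aa)) "X" else aa
        } else ""
        x <- a + take
        cls <- x %% 3L
        j0 <- (x - cls) %/% 3L + 1L
        # prune acceptors whose exon 3 cannot reach the amplicon end cleanly
        suffix_clean <- j0 > last_stop[cls + 1L]
        if (!suffix_clean && length(clean_donors) > 0L) next
        suffix <- substr(trans[[cls + 1L]], j0, nchar(trans[[cls + 1L]]))
        prot <- paste0(prefix, junction, suffix)
        stop_at <- regexpr("*", prot, fixed = TRUE)
        if (stop_at > 0L) prot <- substr(prot, 1L, stop_at - 1L)
        sc <- score_structure_protein(prot, library, mat)
        candidates[[length(candidates) + 1L]] <-
          list(frame = f, donor = g, acceptor = a,
               score = sc$total + .splice_signal_score(seq_chars, g, a))
      }
    }
  }
  if (length(candidates) == 0L) {
    stop("unannotatable amplicon: no GT..NG interval satisfies the ",
         "intron/exon size constraints")
  }
  scores <- vapply(candidates, `[[`, numeric(1), "score")
  best <- which.max(scores)
  ties <- which(scores >= scores[best] - 1e-9)
  if (length(ties) > 1L) {
    listing <- vapply(candidates[ties[seq_len(min(8L, length(ties)))]],
                      function(cd) sprintf("[%d,%d) score %.2f",
                                           cd$donor, cd$acceptor, cd$score),
                      character(1))
    stop(structure(class = c("srnase_ambiguous_structure", "error",
                             "condition"),
                   list(message = paste0(
                          "ambiguous gene structure: ", length(ties),
                          " equally scoring intron candidates: ",
                          paste(listing, collapse = "; ")),
                        call = sys.call(-1))))
  }
  cd <- candidates[[best]]
  gene_structure(exon2 = c(0L, cd$donor),
                 intron2 = c(cd$donor, cd$acceptor),
                 exon3 = c(cd$acceptor, n),
                 frame_offset = cd$frame, sequence = sequence)
}

#' Transfer a gene structure from a close relative
#'
#' Maps the exon/intron boundaries of an annotated reference amplicon onto
#' a target amplicon through a global DNA alignment. Used for alleles whose
#' own translation carries too little signal for [detect_intron()] (e.g.
#' frameshifted pseudogenes), mirroring how such alleles are annotated by
#' comparison with their wild-type counterpart.
#'
#' @param sequence Target amplicon sequence.
#' @param ref_sequence Reference amplicon sequence.
#' @param ref_structure The reference's `gene_structure`.
#' @return A `gene_structure` for the target.
#' @export
transfer_structure <- function(sequence, ref_sequence, ref_structure) {
  aln <- pairwise_align(ref_sequence, sequence, mode = "dna")
  ra <- strsplit(aln$aligned_a, "")[[1]]
  ta <- strsplit(aln$aligned_b, "")[[1]]
  # target coordinate reached after consuming k reference characters
  ref_consumed <- cumsum(ra != "-")
  tgt_consumed <- cumsum(ta != "-")
  map_coord <- function(k) {
    if (k == 0L) return(0L)
    col <- which(ref_consumed >= k)[1]
    as.integer(tgt_consumed[col])
  }
  g <- map_coord(ref_structure$intron2[1])
  a <- map_coord(ref_structure$intron2[2])
  n <- nchar(sequence)
  if (!(g > 0L && a > g && n > a)) {
    stop("transferred boundaries do not fit the target amplicon")
  }
  gene_structure(exon2 = c(0L, g), intron2 = c(g, a), exon3 = c(a, n),
                 frame_offset = ref_structure$frame_offset,
                 sequence = sequence)
}

#' Assess the splice sites of an annotated amplicon
#'
#' Checks the donor (`GT`) and acceptor (`AG`) dinucleotides. When the
#' acceptor is non-canonical the unspliced mRNA is translated through the
#' retained intron, and the number of novel residues appended beyond the
#' exon2-encoded prefix before the first stop codon is reported (an A-to-G
#' change at the intron's penultimate position, turning `AG` into `GG`, is
#' the defect class this models). Cryptic `AG` acceptors within
#' `cryptic_window` bp of the annotated acceptor are listed for follow-up
#' but no choice is made among them.
#'
#' @param sequence Amplicon sequence.
#' @param structure Its `gene_structure`.
#' @param cryptic_window Half-width (bp) of the cryptic-acceptor scan.
#' @return A list of class `splice_assessment`: `donor_ok`, `acceptor_ok`,
#'   `donor_dinucleotide`, `acceptor_dinucleotide`,
#'   `retained_intron_translation` (a `deduced_protein` with
#'   `novel_tail_length` set, or `NULL` for canonical acceptors) and
#'   `cryptic_acceptors` (0-based end-exclusive intron coordinates).
#' @export
assess_splice_sites <- function(sequence, structure, cryptic_window = 50L) {
  donor <- structure$splice5_dinucleotide
  acceptor <- structure$splice3_dinucleotide
  if (is.na(donor)) { # structure built without a sequence
    donor <- substr(sequence, structure$intron2[1] + 1L,
                    structure$intron2[1] + 2L)
    acceptor <- substr(sequence, structure$intron2[2] - 1L,
                       structure$intron2[2])
  }
  retained <- NULL
  cryptic <- integer(0)
  if (!identical(acceptor, "AG")) {
    full <- translate_dna(sequence, structure$frame_offset)
    stop_at <- regexpr("*", full, fixed = TRUE)
    residues <- if (stop_at > 0L) substr(full, 1L, stop_at - 1L) else full
    exon2_codons <- (structure$exon2[2] - structure$frame_offset) %/% 3L
    retained <- structure(
      list(residues = residues,
           stop_position = if (stop_at > 0L) as.integer(stop_at - 1L)
                           else NA_integer_,
           novel_tail_length = max(0L, nchar(residues) - exon2_codons)),
      class = "deduced_protein")
    # candidate rescue acceptors near the annotated (defective) one
    lo <- max(structure$intron2[1] + 2L,
              structure$intron2[2] - cryptic_window)
    hi <- min(nchar(sequence), structure$intron2[2] + cryptic_window)
    window <- substr(sequence, lo + 1L, hi)
    hits <- gregexpr("AG", window, fixed = TRUE)[[1]]
    if (hits[1] != -1L) cryptic <- lo + as.integer(hits) + 1L
  }
  structure(list(donor_ok = identical(donor, "GT"),
                 acceptor_ok = identical(acceptor, "AG"),
                 donor_dinucleotide = donor,
                 acceptor_dinucleotide = acceptor,
                 retained_intron_translation = retained,
                 cryptic_acceptors = cryptic),
            class = "splice_assessment")
}

# Internal: indel runs between two spliced coding sequences, from a global
# DNA alignment. Returns a data frame of runs (0-based reference position,
# length, inserted-in which sequence).
.cds_indel_runs <- function(cds_a, cds_b) {
  aln <- pairwise_align(cds_a, cds_b, mode = "dna")
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  gap <- (a == "-") | (b == "-")
  if (!any(gap)) {
    return(data.frame(position = integer(0), length = integer(0),
                      where = character(0)))
  }
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ref_pos <- cumsum(a != "-")
  data.frame(
    position = vapply(keep, function(k) as.integer(ref_pos[starts[k]]),
                      integer(1)),
    length = r$lengths[keep],
    where = vapply(keep, function(k) {
      if (a[starts[k]] == "-") "a" else "b"
    }, character(1))
  )
}

#' Call the functional status of an allele
#'
#' Combines the annotations of one allele into a single loss-of-function
#' verdict with the precedence: splice defect (non-canonical donor or
#' acceptor) over premature stop (an in-frame stop codon upstream of a
#' detectable C5) over frameshift truncation (an exonic indel of length not
#' divisible by 3 relative to a paired wild-type allele) over putative
#' functional.
#'
#' @param sequence Amplicon sequence.
#' @param structure Its `gene_structure`.
#' @param protein Its `deduced_protein` from [translate_cds()].
#' @param region_map Its `region_map` from [locate_conserved_regions()].
#' @param splice Its `splice_assessment`.
#' @param paired_wildtype Optional list with `allele_id`, `sequence` and
#'   `structure` of a close wild-type relative, used for frameshift
#'   detection by paired comparison.
#' @return A list of class `functional_call`: `status`, `missing_regions`,
#'   `evidence` (character vector), `paired_wildtype` (id or `NA`).
#' @export
call_functional_status <- function(sequence, structure, protein, region_map,
                                   splice, paired_wildtype = NULL) {
  missing <- missing_regions(region_map)
  evidence <- character(0)
  pair_id <- NA_character_
  status <- "putative-functional"

  if (!splice$acceptor_ok || !splice$donor_ok) {
    status <- "splice-defect"
    bad <- c(if (!splice$donor_ok)
               sprintf("donor %s (expected GT)", splice$donor_dinucleotide),
             if (!splice$acceptor_ok)
               sprintf("acceptor %s (expected AG)",
                       splice$acceptor_dinucleotide))
    evidence <- c(evidence, paste("non-canonical splice site:",
                                  paste(bad, collapse = ", ")))
    if (!is.null(splice$retained_intron_translation)) {
      evidence <- c(evidence, sprintf(
        "retained-intron translation adds %d novel residues%s",
        splice$retained_intron_translation$novel_tail_length,
        if (!is.na(splice$retained_intron_translation$stop_position))
          " before a stop codon" else ""))
    }
  } else if (!is.na(protein$stop_position) && "C5" %in% missing) {
    status <- "premature-stop"
    evidence <- c(evidence, sprintf(
      "in-frame stop codon after residue %d, upstream of C5",
      protein$stop_position))
  } else {
    fs <- NULL
    if (!is.null(paired_wildtype)) {
      pair_id <- paired_wildtype$allele_id
      runs <- .cds_indel_runs(
        splice_cds(paired_wildtype$sequence, paired_wildtype$structure),
        splice_cds(sequence, structure))
      fs <- runs[runs$length %% 3L != 0L, , drop = FALSE]
      if (nrow(fs) > 0L) {
        status <- "frameshift-truncated"
        evidence <- c(evidence, sprintf(
          "%d-nt exonic %s at CDS position %d relative to %s",
          fs$length[1],
          ifelse(fs$where[1] == "b", "deletion", "insertion"),
          fs$position[1], pair_id))
      }
    }
    if (status == "putative-functional" && length(missing) > 0L) {
      # A region scoring below threshold while later regions are still
      # present is divergence, not loss: the product is full length. Only
      # a missing suffix of regions signals a truncated product.
      order4 <- c("RHV", "C3", "RC4", "C5")
      present <- setdiff(order4, missing)
      internal <- missing[vapply(missing, function(r) {
        later <- order4[seq.int(match(r, order4), 4L)]
        any(later %in% present)
      }, logical(1))]
      trailing <- setdiff(missing, internal)
      if (length(internal) > 0L) {
        evidence <- c(evidence, paste(
          "diverged below motif threshold (full-length product):",
          paste(internal, collapse = ", ")))
      }
      missing <- trailing
      if (length(trailing) > 0L) {
        status <- "frameshift-truncated"
        evidence <- c(evidence, paste(
          "product ends before", paste(trailing, collapse = ", "),
          "without an identified lesion or paired wild type"))
      }
    }
  }
  if (status == "putative-functional") missing <- character(0)
  structure(list(status = status, missing_regions = missing,
                 evidence = evidence, paired_wildtype = pair_id),
            class = "functional_call")
}

#' @export
print.functional_call <- function(x, ...) {
  cat("functional_call:", x$status,
      if (length(x$missing_regions) > 0L)
        paste0("(missing ", paste(x$missing_regions, collapse = ","), ")")
      else "", "\n")
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

# Internal: synonymous/nonsynonymous change counts along all substitution
# orderings between two codons, averaged (pathway counting). Steps through
# a stop codon count as nonsynonymous.
.codon_path_counts <- function(codon_a, codon_b) {
  tab <- .codon_table()
  diff <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  if (length(diff) == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- if (length(diff) == 1L) list(diff) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      unlist(lapply(seq_along(v),
                    function(i) lapply(perms(v[-i]), function(p) c(v[i], p))),
             recursive = FALSE)
    }
    perms(diff)
  }
  b_chars <- strsplit(codon_b, "")[[1]]
  totals <- vapply(orders, function(ord) {
    cur <- strsplit(codon_a, "")[[1]]
    syn <- 0; nonsyn <- 0
    for (pos in ord) {
      aa_before <- unname(tab[paste(cur, collapse = "")])
      cur[pos] <- b_chars[pos]
      aa_after <- unname(tab[paste(cur, collapse = "")])
      if (!is.na(aa_before) && identical(aa_before, aa_after)) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
    }
    c(syn, nonsyn)
  }, numeric(2))
  c(syn = mean(totals[1, ]), nonsyn = mean(totals[2, ]))
}

#' Count synonymous and nonsynonymous substitutions between paired alleles
#'
#' Codon-by-codon comparison of the spliced coding sequences of two closely
#' related alleles (e.g. a wild type and its mutant derivative) in their
#' shared reading frame. Codons differing at a single position are
#' classified directly; codons differing at several positions are counted
#' by enumerating all substitution orderings and averaging, in which case
#' counts may be fractional and `fractional` is set.
#'
#' If the coding sequences differ in length, the exonic indels are counted
#' and substitutions are only tallied on the alignment prefix preceding the
#' first indel.
#'
#' @param wildtype,mutant Amplicon sequences.
#' @param structure_wt `gene_structure` of the wild type.
#' @param structure_mut `gene_structure` of the mutant; defaults to the
#'   wild-type structure (identical exon spans).
#' @return A list with `synonymous`, `nonsynonymous`, `indels` and
#'   `fractional`.
#' @export
count_syn_nonsyn <- function(wildtype, mutant, structure_wt,
                             structure_mut = structure_wt) {
  cds_a <- splice_cds(wildtype, structure_wt)
  cds_b <- splice_cds(mutant, structure_mut)
  f <- structure_wt$frame_offset
  cds_a <- substr(cds_a, f + 1L, nchar(cds_a))
  cds_b <- substr(cds_b, structure_mut$frame_offset + 1L, nchar(cds_b))
  indels <- 0L
  if (nchar(cds_a) != nchar(cds_b)) {
    runs <- .cds_indel_runs(cds_a, cds_b)
    indels <- nrow(runs)
    cut <- min(runs$position)
    cds_a <- substr(cds_a, 1L, cut)
    cds_b <- substr(cds_b, 1L, cut)
  }
  n_codons <- min(nchar(cds_a), nchar(cds_b)) %/% 3L
  syn <- 0; nonsyn <- 0; fractional <- FALSE
  if (n_codons > 0L) {
    starts <- seq.int(1L, by = 3L, length.out = n_codons)
    ca <- substring(cds_a, starts, starts + 2L)
    cb <- substring(cds_b, starts, starts + 2L)
    for (k in which(ca != cb)) {
      counts <- .codon_path_counts(ca[k], cb[k])
      syn <- syn + counts["syn"]
      nonsyn <- nonsyn + counts["nonsyn"]
      if (counts["syn"] %% 1 != 0) fractional <- TRUE
    }
  }
  list(synonymous = unname(syn), nonsynonymous = unname(nonsyn),
       indels = indels, fractional = fractional)
}

#' Annotate a set of alleles end to end
#'
#' Runs [detect_intron()], [translate_cds()], [locate_conserved_regions()],
#' [assess_splice_sites()] and [call_functional_status()] over an allele
#' table. Because near-identical amplicons must share a gene structure,
#' alleles at or above `pair_floor` percent amplicon identity are
#' clustered and reconciled against the cluster's best-supported member
#' (clean gene model first, strongest splice-signal context as
#' tie-break): members whose own detection is ambiguous, unclean, or
#' discordant with that reference beyond `boundary_tol` receive the
#' reference structure via [transfer_structure()], which handles both
#' frameshifted pseudogenes (every candidate scores alike) and decoy
#' ORFs that splice a lesion out of frame. The cluster reference also
#' serves as the paired wild type for frameshift calling.
#'
#' @param records Allele table (see [read_fasta()]).
#' @param library Motif library.
#' @param pair_floor Minimum amplicon identity (percent) for wild-type
#'   pairing.
#' @param boundary_tol Maximum disagreement (bp, summed over the two
#'   intron boundaries) between an allele's own detection and the
#'   structure mapped from its clean relative before the transferred
#'   structure overrules the self-detection.
#' @return An object of class `allele_annotations`: a named list (one
#'   element per allele) of lists with `allele_id`, `structure`, `protein`,
#'   `region_map`, `splice`, `call`, `transferred_from`.
#' @export
annotate_alleles <- function(records, library = default_motif_library(),
                             pair_floor = 97, boundary_tol = 6L) {
  validate_alleles(records)
  n <- nrow(records)
  seq_of <- stats::setNames(records$sequence, records$allele_id)
  ann <- stats::setNames(vector("list", n), records$allele_id)
  for (i in seq_len(n)) {
    id <- records$allele_id[i]
    res <- tryCatch(
      detect_intron(records$sequence[i], library),
      srnase_ambiguous_structure = function(e) e
    )
    ann[[id]] <- list(allele_id = id,
                      structure = if (inherits(res, "condition")) NULL
                                  else res,
                      transferred_from = NA_character_)
  }
  # An allele's own annotation is trustworthy when it yields a clean gene
  # model: canonical splice sites, full-length stop-free translation and
  # all conserved regions present.
  is_clean <- function(a) {
    if (is.null(a$structure)) return(FALSE)
    s <- a$structure
    if (!identical(s$splice5_dinucleotide, "GT") ||
        !identical(s$splice3_dinucleotide, "AG")) return(FALSE)
    prot <- translate_cds(seq_of[[a$allele_id]], s)
    if (!is.na(prot$stop_position)) return(FALSE)
    rm <- tryCatch(locate_conserved_regions(prot, library),
                   error = function(e) NULL)
    !is.null(rm) && length(missing_regions(rm)) == 0L
  }
  clean <- vapply(ann, is_clean, logical(1))
  if (!any(clean)) {
    stop("no allele could be annotated independently with a clean gene ",
         "model")
  }
  # Splice-signal strength of an allele's own annotated sites (donor
  # consensus, polypyrimidine tract, canonical acceptor); genuine sites
  # carry consensus context, decoy intervals usually do not.
  signal <- vapply(records$allele_id, function(id) {
    s <- ann[[id]]$structure
    if (is.null(s)) return(-Inf)
    .splice_signal_score(strsplit(seq_of[[id]], "")[[1]],
                         s$intron2[1], s$intron2[2])
  }, numeric(1))

  # Near-identical amplicons must share a gene structure, so alleles are
  # clustered at >= pair_floor percent amplicon identity (only pairs of
  # near-equal length can qualify) and each cluster is reconciled against
  # its best-supported member: clean first, strongest splice signal as
  # tie-break. A cluster member whose own detection is either unclean or
  # discordant with the reference (for example a lesion-carrying copy
  # whose detection restored a decoy ORF by splicing the lesion out) gets
  # the reference structure transferred; the reference also serves as its
  # paired wild type.
  ids <- records$allele_id
  lens <- nchar(records$sequence)
  parent <- stats::setNames(seq_len(n), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (abs(lens[i] - lens[j]) > 30L) next
        pid <- identity_percent(pairwise_align(seq_of[[ids[i]]],
                                               seq_of[[ids[j]]],
                                               mode = "dna"))
        if (pid >= pair_floor) parent[find(i)] <- find(j)
      }
    }
  }
  paired_with <- stats::setNames(rep(NA_character_, n), ids)
  comp <- vapply(seq_len(n), find, numeric(1))
  for (cl in split(seq_len(n), comp)) {
    if (length(cl) < 2L) next
    score <- clean[cl] * 1e6 + signal[cl]
    ref <- cl[which.max(score)]
    if (!clean[ref]) next  # no trustworthy member to reconcile against
    for (i in setdiff(cl, ref)) {
      id <- ids[i]
      transferred <- transfer_structure(seq_of[[id]], seq_of[[ids[ref]]],
                                        ann[[ids[ref]]]$structure)
      own <- ann[[id]]$structure
      discordant <- is.null(own) ||
        abs(own$intron2[1] - transferred$intron2[1]) +
          abs(own$intron2[2] - transferred$intron2[2]) > boundary_tol
      if (discordant && (!clean[i] || signal[i] < signal[ref])) {
        ann[[id]]$structure <- transferred
        ann[[id]]$transferred_from <- ids[ref]
      }
      paired_with[id] <- ids[ref]
    }
  }
  for (id in ids[!clean]) {
    if (is.null(ann[[id]]$structure)) {
      stop("allele ", id, " is ambiguous and has no close relative ",
           "at or above ", pair_floor, "% identity to transfer a ",
           "structure from")
    }
  }
  for (id in records$allele_id) {
    a <- ann[[id]]
    a$protein <- translate_cds(seq_of[[id]], a$structure)
    a$region_map <- locate_conserved_regions(a$protein, library)
    a$splice <- assess_splice_sites(seq_of[[id]], a$structure)
    paired <- NULL
    if (!is.na(paired_with[id])) {
      wid <- paired_with[[id]]
      paired <- list(allele_id = wid, sequence = seq_of[[wid]],
                     structure = ann[[wid]]$structure)
    }
    a$call <- call_functional_status(seq_of[[id]], a$structure, a$protein,
                                     a$region_map, a$splice, paired)
    ann[[id]] <- a
  }
  structure(ann, class = "allele_annotations")
}

#' Summarize allele annotations as a table
#'
#' @param x An `allele_annotations` object.
#' @param ... Unused.
#' @return Data frame with one row per allele: span widths, protein length,
#'   splice dinucleotides, functional status and evidence.
#' @export
as.data.frame.allele_annotations <- function(x, ...) {
  rows <- lapply(x, function(a) {
    s <- a$structure
    data.frame(
      allele_id = a$allele_id,
      amplicon_bp = s$exon3[2],
      exon2_bp = s$exon2[2] - s$exon2[1],
      intron2_bp = intron_length(s),
      exon3_bp = s$exon3[2] - s$exon3[1],
      protein_aa = nchar(a$protein$residues),
      splice5 = s$splice5_dinucleotide,
      splice3 = s$splice3_dinucleotide,
      status = a$call$status,
      missing_regions = paste(a$call$missing_regions, collapse = ","),
      paired_wildtype = a$call$paired_wildtype,
      transferred_from = a$transferred_from,
      evidence = paste(a$call$evidence, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write annotated gene structures as GFF3
#'
#' One `exon`/`intron` feature per span, 1-based inclusive coordinates,
#' with each allele as its own landmark sequence.
#'
#' @param annotations An `allele_annotations` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff <- function(annotations, path) {
  lines <- "##gff-version 3"
  for (a in annotations) {
    s <- a$structure
    feat <- function(type, tag, span, note = "") {
      sprintf("%s\tsrnase\t%s\t%d\t%d\t.\t+\t.\tID=%s_%s%s",
              a$allele_id, type, span[1] + 1L, span[2], a$allele_id, tag,
              note)
    }
    lines <- c(lines,
               feat("exon", "exon2", s$exon2),
               feat("intron", "intron2", s$intron2,
                    sprintf(";splice_sites=%s..%s", s$splice5_dinucleotide,
                            s$splice3_dinucleotide)),
               feat("exon", "exon3", s$exon3))
  }
  writeLines(lines, path)
  invisible(path)
}
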