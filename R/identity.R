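# Pairwise identity at three levels (exon nucleotide, deduced amino acid,
# second intron) and trans-specificity classification.

#' Global pairwise alignment
#'
#' Needleman-Wunsch alignment with affine gap costs. Protein mode scores
#' with a PAM-family matrix (default PAM250, gap open 10 / extend 0.5); DNA
#' mode with match +2 / mismatch -1 (gap open 10 / extend 0.2). These are
#' the ClustalW-family defaults; all parameters are recorded in the result
#' so identity values are auditable.
#'
#' @param seq_a,seq_b Sequences (non-empty strings).
#' @param mode `"dna"` or `"protein"`.
#' @param matrix_name Protein scoring matrix name.
#' @param match,mismatch DNA scores.
#' @param gap_open,gap_extend Affine gap penalties (positive); defaults
#'   depend on `mode`.
#' @return A list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length strings with `-` for gaps), `score`, `mode`, `params`.
#' @export
pairwise_align <- function(seq_a, seq_b, mode = c("dna", "protein"),
                           matrix_name = "PAM250", match = 2, mismatch = -1,
                           gap_open = NULL, gap_extend = NULL) {
  mode <- match.arg(mode)
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("cannot align empty sequences")
  }
  if (mode == "protein") {
    if (is.null(gap_open)) gap_open <- 10
    if (is.null(gap_extend)) gap_extend <- 0.5
    mat <- substitution_matrix(matrix_name)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    params <- list(matrix = matrix_name, gap_open = gap_open,
                   gap_extend = gap_extend)
  } else {
    if (is.null(gap_open)) gap_open <- 10
    if (is.null(gap_extend)) gap_extend <- 0.2
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    params <- list(match = match, mismatch = mismatch, gap_open = gap_open,
                   gap_extend = gap_extend)
  }
  structure(list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
                 aligned_b = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa), mode = mode,
                 params = params),
            class = "pairwise_alignment")
}

#' Percent identity of a pairwise alignment
#'
#' Default denominator convention (`"aligned"`): matches divided by the
#' number of alignment columns containing at least one residue, so gap
#' columns count as mismatches. Alternatives: `"nogap"` excludes all
#' gapped columns; `"shorter"` divides by the shorter sequence length. The
#' convention used is recorded by callers that report identities.
#'
#' @param alignment A `pairwise_alignment`.
#' @param denominator Convention, see above.
#' @return Identity percentage in \[0, 100\].
#' @export
identity_percent <- function(alignment,
                             denominator = c("aligned", "nogap",
                                             "shorter")) {
  denominator <- match.arg(denominator)
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  if (length(a) == 0L) stop("zero-length alignment")
  matches <- sum(a == b & a != "-")
  denom <- switch(denominator,
    aligned = sum(a != "-" | b != "-"),
    nogap = sum(a != "-" & b != "-"),
    shorter = min(sum(a != "-"), sum(b != "-"))
  )
  if (denom == 0L) stop("zero-length alignment")
  100 * matches / denom
}

#' Build the three-level identity matrices of an allele set
#'
#' For every allele pair, computes percent identity between (i) the
#' concatenated exon nucleotide sequences, (ii) the deduced amino-acid
#' sequences and (iii) the second intron nucleotide sequences, from global
#' pairwise alignments.
#'
#' @param records Allele table.
#' @param annotations `allele_annotations` for the same alleles.
#' @param denominator Identity denominator convention, see
#'   [identity_percent()].
#' @return An object of class `identity_matrices`: list with symmetric
#'   matrices `exon_nt`, `aa`, `intron_nt` (diagonal 100), and `params`.
#' @export
build_identity_matrices <- function(records, annotations,
                                    denominator = "aligned") {
  ids <- records$allele_id
  missing_ann <- setdiff(ids, names(annotations))
  if (length(missing_ann) > 0L) {
    stop("unannotated allele: ", paste(missing_ann, collapse = ", "))
  }
  seq_of <- stats::setNames(records$sequence, ids)
  exon <- vapply(ids, function(id)
    splice_cds(seq_of[[id]], annotations[[id]]$structure), character(1))
  intr <- vapply(ids, function(id)
    span_seq(seq_of[[id]], annotations[[id]]$structure$intron2),
    character(1))
  prot <- vapply(ids, function(id)
    annotations[[id]]$protein$residues, character(1))

  n <- length(ids)
  level <- function(seqs, mode) {
    m <- matrix(100, n, n, dimnames = list(ids, ids))
    if (n < 2L) return(m)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        pid <- identity_percent(
          pairwise_align(seqs[[i]], seqs[[j]], mode = mode),
          denominator = denominator)
        m[i, j] <- pid
        m[j, i] <- pid
      }
    }
    m
  }
  structure(list(exon_nt = level(exon, "dna"),
                 aa = level(prot, "protein"),
                 intron_nt = level(intr, "dna"),
                 params = list(denominator = denominator,
                               protein_matrix = "PAM250",
                               dna_match = 2, dna_mismatch = -1)),
            class = "identity_matrices")
}

#' Summary statistics of identity matrices
#'
#' Mean, minimum and maximum over off-diagonal pairs for each level, with
#' the allele pairs attaining the extremes.
#'
#' @param matrices An `identity_matrices` object.
#' @return Data frame with columns `level`, `mean`, `min`, `min_pair`,
#'   `max`, `max_pair`, `n_pairs`.
#' @export
summarize_identity <- function(matrices) {
  one <- function(m, level) {
    ut <- upper.tri(m)
    vals <- m[ut]
    if (length(vals) == 0L) {
      return(data.frame(level = level, mean = NA_real_, min = NA_real_,
                        min_pair = NA_character_, max = NA_real_,
                        max_pair = NA_character_, n_pairs = 0L))
    }
    idx <- which(ut, arr.ind = TRUE)
    pair_name <- function(k) paste(rownames(m)[idx[k, 1]],
                                   colnames(m)[idx[k, 2]], sep = "-")
    data.frame(level = level, mean = mean(vals), min = min(vals),
               min_pair = pair_name(which.min(vals)), max = max(vals),
               max_pair = pair_name(which.max(vals)),
               n_pairs = length(vals), stringsAsFactors = FALSE)
  }
  rbind(one(matrices$exon_nt, "exon_nt"),
        one(matrices$aa, "aa"),
        one(matrices$intron_nt, "intron_nt"))
}

#' Classify cross-species allele pairs as trans-specific
#'
#' Applies a multi-evidence rule to every pair of alleles carrying
#' different species tags: a pair is `supported` when its deduced
#' amino-acid identity is at least `aa_threshold` (default 96 percent) and,
#' when a tree is supplied, the two alleles are mutually nearest in it;
#' `ambiguous` when the amino-acid identity falls in the
#' `ambiguous_range` band, or exceeds the threshold while the second-intron
#' identity stays below `intron_floor` or the tree does not place the pair
#' together; `unsupported` otherwise. The number of amino-acid replacements
#' inside the RHV is attached as a caution flag when annotations are given,
#' since RHV replacements argue for changed allele specificity.
#'
#' @param matrices `identity_matrices` over all alleles (both species).
#' @param records Allele table with `species_tag` filled in.
#' @param tree Optional `phylo` tree whose tips are allele ids; when
#'   `NULL`, verdicts rest on identities alone and are flagged `no-tree`.
#' @param annotations Optional `allele_annotations`, enables the RHV
#'   replacement count.
#' @param aa_threshold,ambiguous_range,intron_floor Thresholds in percent.
#' @return Data frame with one row per cross-species pair: ids, species,
#'   identities, `rhv_replacements`, `mutually_nearest`, `verdict`, `note`.
#' @export
classify_trans_specific <- function(matrices, records, tree = NULL,
                                    annotations = NULL, aa_threshold = 96,
                                    ambiguous_range = c(92, 96),
                                    intron_floor = 90) {
  ids <- rownames(matrices$aa)
  species <- stats::setNames(records$species_tag, records$allele_id)[ids]
  pairs <- which(upper.tri(matrices$aa), arr.ind = TRUE)
  keep <- which(species[pairs[, 1]] != species[pairs[, 2]] &
                  !is.na(species[pairs[, 1]]) & !is.na(species[pairs[, 2]]))
  if (length(keep) == 0L) {
    return(data.frame(allele_a = character(), allele_b = character(),
                      species_a = character(), species_b = character(),
                      aa_identity = numeric(), intron_identity = numeric(),
                      rhv_replacements = integer(),
                      mutually_nearest = logical(), verdict = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  pairs <- pairs[keep, , drop = FALSE]

  coph <- NULL
  if (!is.null(tree)) coph <- stats::cophenetic(tree)
  mutual_nearest <- function(a, b) {
    if (is.null(coph) || !(a %in% rownames(coph)) ||
        !(b %in% rownames(coph))) return(NA)
    da <- coph[a, setdiff(colnames(coph), a)]
    db <- coph[b, setdiff(colnames(coph), b)]
    names(which.min(da)) == b && names(which.min(db)) == a
  }
  rhv_count <- function(a, b) {
    if (is.null(annotations)) return(NA_integer_)
    ev <- enumerate_substitutions(annotations[[a]]$protein$residues,
                                  annotations[[b]]$protein$residues,
                                  annotations[[a]]$region_map,
                                  pair_id = paste(a, b, sep = "-"))
    sum(ev$event_type == "substitution" & ev$region == "RHV")
  }

  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- ids[pairs[k, 1]]; b <- ids[pairs[k, 2]]
    aa <- matrices$aa[a, b]
    intr <- matrices$intron_nt[a, b]
    mn <- mutual_nearest(a, b)
    note <- character(0)
    if (is.null(coph)) note <- c(note, "no-tree")
    verdict <- "unsupported"
    if (aa >= aa_threshold) {
      if (intr < intron_floor) {
        verdict <- "ambiguous"
        note <- c(note, sprintf("intron identity %.1f below floor %.1f",
                                intr, intron_floor))
      } else if (isFALSE(mn)) {
        verdict <- "ambiguous"
        note <- c(note, "pair not mutually nearest in tree")
      } else {
        verdict <- "supported"
      }
    } else if (aa >= ambiguous_range[1] && aa < ambiguous_range[2]) {
      verdict <- "ambiguous"
    }
    rhv <- rhv_count(a, b)
    if (!is.na(rhv) && rhv > 0L) {
      note <- c(note, sprintf("%d RHV replacement(s)", rhv))
    }
    data.frame(allele_a = a, allele_b = b,
               species_a = unname(species[a]),
               species_b = unname(species[b]),
               aa_identity = aa, intron_identity = intr,
               rhv_replacements = rhv,
               mutually_nearest = if (is.na(mn)) NA else mn,
               verdict = verdict,
               note = paste(note, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
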