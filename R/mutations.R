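# Region-assigned amino-acid replacement analysis: which structural
# regions of the S-RNase accumulate replacements, and how often those
# replacements are non-conservative (negative PAM score).

REGION_LABELS <- c("C2", "C2-RHV", "RHV", "RHV-C3", "C3", "C3-RC4", "RC4",
                   "RC4-C5", "C5")

#' Enumerate amino-acid differences between two aligned proteins
#'
#' Globally aligns the two deduced proteins and emits one event per
#' differing column: substitutions carry the residue pair and their
#' conservativeness (non-conservative iff the substitution-matrix score is
#' negative); maximal runs of consecutive gap columns collapse into a
#' single indel event. Events are labelled with the structural region of
#' the reference (first) sequence at that column.
#'
#' @param protein_a Reference protein (string); region labels come from
#'   its coordinates.
#' @param protein_b Second protein (string).
#' @param region_map `region_map` of the reference protein.
#' @param pair_id Identifier stored with each event.
#' @param matrix_name Matrix used for conservativeness classification.
#' @return Data frame of class `mutation_events`: `pair_id`, `column`
#'   (0-based alignment column), `ref_position` (0-based residue in the
#'   reference), `region`, `residue_a`, `residue_b`, `event_type`
#'   (`substitution`/`indel`), `conservativeness` (`conservative`,
#'   `non-conservative`, or `NA` for indels and non-standard residues).
#' @export
enumerate_substitutions <- function(protein_a, protein_b, region_map,
                                    pair_id = "pair",
                                    matrix_name = "PAM250") {
  if (is.null(region_map)) stop("region_map is required")
  aln <- pairwise_align(protein_a, protein_b, mode = "protein",
                        matrix_name = matrix_name)
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  ref_pos <- cumsum(a != "-") - 1L  # 0-based reference residue at column
  ref_pos[a == "-"] <- NA_integer_
  label_at <- function(col) {
    # indel columns inherit the label of the nearest preceding reference
    # residue (or the first residue for a leading gap)
    p <- ref_pos[col]
    if (is.na(p)) {
      prev <- which(!is.na(ref_pos[seq_len(col)]))
      p <- if (length(prev) > 0L) ref_pos[max(prev)] else 0L
    }
    region_of(region_map, min(p, region_map$protein_length - 1L))
  }
  gap <- (a == "-") | (b == "-")
  events <- list()
  # substitutions
  for (col in which(!gap & a != b)) {
    cons <- classify_replacement(a[col], b[col], matrix_name,
                                 .quiet = TRUE)
    events[[length(events) + 1L]] <- data.frame(
      pair_id = pair_id, column = col - 1L, ref_position = ref_pos[col],
      region = label_at(col), residue_a = a[col], residue_b = b[col],
      event_type = "substitution", conservativeness = cons,
      stringsAsFactors = FALSE)
  }
  # indels: one event per maximal gap run
  if (any(gap)) {
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      col <- starts[k]
      events[[length(events) + 1L]] <- data.frame(
        pair_id = pair_id, column = col - 1L,
        ref_position = ref_pos[col], region = label_at(col),
        residue_a = paste(a[starts[k]:ends[k]], collapse = ""),
        residue_b = paste(b[starts[k]:ends[k]], collapse = ""),
        event_type = "indel", conservativeness = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) {
    out <- data.frame(pair_id = character(), column = integer(),
                      ref_position = integer(), region = character(),
                      residue_a = character(), residue_b = character(),
                      event_type = character(),
                      conservativeness = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, events)
    out <- out[order(out$column), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mutation_events", class(out))
  out
}

#' Classify an amino-acid replacement as conservative or not
#'
#' A replacement is non-conservative iff its score in the chosen
#' PAM-family matrix is negative; otherwise conservative. The
#' classification is symmetric in the two residues.
#'
#' @param residue_a,residue_b Single standard amino-acid letters (must
#'   differ).
#' @param matrix_name Matrix name (default PAM250; PAM120 or a BLOSUM can
#'   be chosen for sensitivity analysis).
#' @param .quiet Suppress the warning for non-standard residues.
#' @return `"conservative"`, `"non-conservative"`, or `NA` (with a
#'   warning) when either residue is not a standard amino acid.
#' @export
classify_replacement <- function(residue_a, residue_b,
                                 matrix_name = "PAM250", .quiet = FALSE) {
  if (identical(residue_a, residue_b)) {
    stop("not a replacement: residues are identical (", residue_a, ")")
  }
  mat <- substitution_matrix(matrix_name)
  standard <- setdiff(rownames(mat), c("X", "*", "B", "Z", "J", "U", "O"))
  if (!(residue_a %in% standard) || !(residue_b %in% standard)) {
    if (!.quiet) {
      warning("non-standard residue in replacement ", residue_a, "/",
              residue_b, "; conservativeness not defined")
    }
    return(NA_character_)
  }
  if (mat[residue_a, residue_b] < 0) "non-conservative" else "conservative"
}

#' Region frequency profile of mutation events
#'
#' Aggregates mutation events into the per-region profile: substitution
#' and indel counts, each region's share of all substitutions, and the
#' non-conservative fraction per region. Indels are tallied but excluded
#' from the percentage base, since conservativeness is undefined for gaps.
#' Raw fractions are returned; rounding is left to report time.
#'
#' @param events A `mutation_events` data frame (possibly concatenated
#'   over many pairs); must contain at least one event.
#' @return Data frame with one row per region label: `region`,
#'   `substitutions`, `indels`, `share_pct`, `non_conservative`,
#'   `non_conservative_pct`.
#' @export
region_frequency_table <- function(events) {
  if (nrow(events) == 0L) stop("no events")
  subs <- events[events$event_type == "substitution", , drop = FALSE]
  total <- nrow(subs)
  rows <- lapply(REGION_LABELS, function(reg) {
    in_reg <- subs[subs$region == reg, , drop = FALSE]
    nc <- sum(in_reg$conservativeness == "non-conservative", na.rm = TRUE)
    n_class <- sum(!is.na(in_reg$conservativeness))
    data.frame(
      region = reg,
      substitutions = nrow(in_reg),
      indels = sum(events$event_type == "indel" & events$region == reg),
      share_pct = if (total > 0L) 100 * nrow(in_reg) / total else NA_real_,
      non_conservative = nc,
      non_conservative_pct = if (n_class > 0L) 100 * nc / n_class
                             else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select allele pairs for the mutation-frequency analysis
#'
#' Default roster: every allele pair (within or across species tags) whose
#' deduced amino-acid identity is at least `aa_floor` percent, plus every
#' wild-type/mutant pair (alleles whose id is another id with an `m`
#' suffix). An explicit two-column roster overrides the rule entirely.
#'
#' @param records Allele table.
#' @param matrices `identity_matrices` over the same alleles.
#' @param aa_floor Identity floor in percent (default 80).
#' @param pairs_file Optional path to a TSV with columns `allele_a`,
#'   `allele_b`; when given, it is used verbatim.
#' @return Data frame with columns `allele_a`, `allele_b`.
#' @export
select_pairs <- function(records, matrices, aa_floor = 80,
                         pairs_file = NULL) {
  if (!is.null(pairs_file)) {
    roster <- utils::read.delim(pairs_file, stringsAsFactors = FALSE)
    if (!all(c("allele_a", "allele_b") %in% names(roster))) {
      stop("pairs file must have columns allele_a, allele_b")
    }
    return(roster[, c("allele_a", "allele_b")])
  }
  ids <- rownames(matrices$aa)
  idx <- which(upper.tri(matrices$aa), arr.ind = TRUE)
  keep <- matrices$aa[idx] >= aa_floor
  out <- data.frame(allele_a = ids[idx[keep, 1]],
                    allele_b = ids[idx[keep, 2]],
                    stringsAsFactors = FALSE)
  # wild-type/mutant pairs are always analysed
  mut <- grep("m$", ids, value = TRUE)
  for (m in mut) {
    wt <- sub("m$", "", m)
    if (wt %in% ids) {
      pr <- sort(c(wt, m))
      have <- any(out$allele_a == pr[1] & out$allele_b == pr[2]) ||
        any(out$allele_a == pr[2] & out$allele_b == pr[1])
      if (!have) {
        out <- rbind(out, data.frame(allele_a = pr[1], allele_b = pr[2],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Mutation-region profile for a set of allele pairs
#'
#' Convenience wrapper: enumerates the events of every pair in the roster
#' (reference = the lexicographically first allele of each pair, a
#' deterministic convention) and aggregates them with
#' [region_frequency_table()].
#'
#' @param pairs Data frame with `allele_a`, `allele_b`.
#' @param annotations `allele_annotations` covering all alleles in
#'   `pairs`.
#' @param matrix_name Conservativeness matrix.
#' @return A list with `events` (all pairs concatenated) and `profile`
#'   (the region frequency table).
#' @export
mutation_region_profile <- function(pairs, annotations,
                                    matrix_name = "PAM250") {
  ev <- lapply(seq_len(nrow(pairs)), function(k) {
    pr <- sort(c(pairs$allele_a[k], pairs$allele_b[k]))
    a <- annotations[[pr[1]]]
    b <- annotations[[pr[2]]]
    if (is.null(a) || is.null(b)) {
      stop("pair references unannotated allele: ",
           paste(pr, collapse = "-"))
    }
    enumerate_substitutions(a$protein$residues, b$protein$residues,
                            a$region_map,
                            pair_id = paste(pr, collapse = "-"),
                            matrix_name = matrix_name)
  })
  events <- do.call(rbind, ev)
  list(events = events, profile = region_frequency_table(events))
}

#' Bar chart of the region mutation profile
#'
#' Conservative and non-conservative replacement counts per region,
#' side by side, in region order along the protein.
#'
#' @param profile Output of [region_frequency_table()].
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_region_profile <- function(profile, ...) {
  h <- rbind(conservative = profile$substitutions - profile$non_conservative,
             `non-conservative` = profile$non_conservative)
  colnames(h) <- profile$region
  graphics::barplot(h, beside = TRUE, legend.text = TRUE,
                    ylab = "amino acid replacements", las = 2, ...)
}
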