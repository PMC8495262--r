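# Conserved-region motif library and region maps on the deduced protein.
#
# Rosaceous S-RNases carry conserved regions C1-C5; amplicons analysed here
# start inside C2 and end in C5, with the hypervariable region (RHV)
# between C2 and C3 and the rosaceous conserved region RC4 between C3 and
# C5. Motifs are scored ungapped against a substitution matrix and placed
# in order; the RHV has no consensus and is assigned positionally.

#' Default conserved-region motif library
#'
#' Consensus amino-acid motifs for C2, C3, RC4 and C5 with their score
#' threshold, the positional definition of the RHV, and the expected
#' inter-motif spacings used to discriminate between candidate gene
#' structures. The shipped consensus set is the one used by the synthetic
#' family generator; for real data the library can be loaded from a YAML
#' file ([load_motif_library()]) so the patterns remain editable
#' configuration rather than hard-coded constants.
#'
#' @param matrix_name Substitution matrix used for motif scoring.
#' @return A list of class `motif_library` with elements `motifs` (named
#'   character vector), `threshold` (fraction of the motif self-score, in
#'   (0, 1]), `rhv_offset`/`rhv_length` (residues; RHV starts `rhv_offset`
#'   residues after the end of C2), `expected_gaps` (expected residue
#'   spacing C2-C3, C3-RC4, RC4-C5) and `width_penalty` (score deducted per
#'   residue of spacing deviation when comparing candidate structures).
#' @export
default_motif_library <- function(matrix_name = "PAM250") {
  lib <- list(
    motifs = c(C2 = "FTVHGLWPSN",
               C3 = "FWEHEWNKHGTC",
               RC4 = "IWSKQWEPQL",
               C5 = "CFDSTIQNCH"),
    threshold = 0.6,
    rhv_offset = 12L,
    rhv_length = 12L,
    expected_gaps = c(C2.C3 = 34L, C3.RC4 = 14L, RC4.C5 = 54L),
    width_penalty = 0.75,
    matrix_name = matrix_name
  )
  class(lib) <- "motif_library"
  lib
}

#' Load a motif library from YAML
#'
#' Reads a library with the same fields as [default_motif_library()];
#' omitted fields fall back to the defaults, unknown fields are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `motif_library`.
#' @export
load_motif_library <- function(path) {
  raw <- yaml::read_yaml(path)
  lib <- default_motif_library()
  known <- setdiff(names(lib), "motifs")
  unknown <- setdiff(names(raw), c(known, "motifs"))
  if (length(unknown) > 0L) {
    stop("unknown motif library fields: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$motifs)) lib$motifs[names(raw$motifs)] <- unlist(raw$motifs)
  for (k in intersect(known, names(raw))) lib[[k]] <- raw[[k]]
  if (any(!nzchar(lib$motifs))) stop("motif patterns must be non-empty")
  if (lib$threshold <= 0 || lib$threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  lib
}

# Encode an amino-acid string as row indices into a scoring matrix.
# Unknown letters (X, *) get index NA and score 0 at lookup time.
.aa_encode <- function(residues, mat) {
  match(strsplit(residues, "")[[1]], rownames(mat))
}

# Score of `motif` placed at every start position of `protein_idx`
# (encoded); vectorized lookup, NA residues contribute 0.
.motif_profile <- function(protein_idx, motif_idx, mat) {
  n <- length(protein_idx)
  m <- length(motif_idx)
  if (n < m) return(numeric(0))
  starts <- seq_len(n - m + 1L)
  scores <- numeric(length(starts))
  for (k in seq_len(m)) {
    v <- mat[cbind(motif_idx[k], protein_idx[starts + k - 1L])]
    v[is.na(v)] <- 0
    scores <- scores + v
  }
  scores
}

.motif_self_score <- function(motif, mat) {
  idx <- match(strsplit(motif, "")[[1]], rownames(mat))
  sum(diag(mat)[idx])
}

#' Place the conserved motifs on a deduced protein
#'
#' Greedy ordered placement: each motif (C2, C3, RC4, C5) is placed at its
#' best-scoring ungapped position after the end of the previously placed
#' motif. A motif scoring below `threshold` times its self-score is marked
#' absent and does not constrain later motifs.
#'
#' @param residues Amino-acid string.
#' @param library A `motif_library`.
#' @return A data frame with one row per motif: `region`, `start`, `end`
#'   (0-based half-open, `NA` when absent), `score`, `self_score`,
#'   `present`.
#' @export
place_motifs <- function(residues, library = default_motif_library()) {
  mat <- substitution_matrix(library$matrix_name)
  pidx <- .aa_encode(residues, mat)
  from <- 0L
  out <- lapply(names(library$motifs), function(region) {
    motif <- library$motifs[[region]]
    midx <- match(strsplit(motif, "")[[1]], rownames(mat))
    prof <- .motif_profile(pidx, midx, mat)
    self <- sum(diag(mat)[midx])
    ok <- seq_along(prof) - 1L >= from   # 0-based candidate starts
    if (!length(prof) || !any(ok)) {
      return(data.frame(region = region, start = NA_integer_,
                        end = NA_integer_, score = -Inf, self_score = self,
                        present = FALSE))
    }
    cand <- which(ok)
    best <- cand[which.max(prof[cand])]
    score <- prof[best]
    present <- score >= library$threshold * self
    if (present) from <<- best - 1L + length(midx)
    data.frame(region = region,
               start = if (present) best - 1L else NA_integer_,
               end = if (present) best - 1L + length(midx) else NA_integer_,
               score = score, self_score = self, present = present)
  })
  do.call(rbind, out)
}

#' Build the region map of a deduced protein
#'
#' Places the conserved motifs, assigns the RHV positionally between C2 and
#' C3 using the library's reference offsets, and derives the inter-region
#' segments by complementation so that every residue belongs to exactly one
#' labelled span. Residues after the last present region are absorbed into
#' the trailing segment (or into C5 when it is present and terminal), so
#' the partition property holds for truncated proteins as well.
#'
#' @param protein A `deduced_protein` or an amino-acid string.
#' @param library A `motif_library`.
#' @return An object of class `region_map`: list with `spans` (named list
#'   of 0-based half-open intervals; absent regions are `NULL`), `labels`
#'   (character vector of length `nchar(protein)` giving each residue's
#'   region or segment) and `protein_length`.
#' @export
locate_conserved_regions <- function(protein,
                                     library = default_motif_library()) {
  residues <- if (inherits(protein, "deduced_protein")) protein$residues
              else protein
  n <- nchar(residues)
  placements <- place_motifs(residues, library)
  rownames(placements) <- placements$region
  if (!placements["C2", "present"]) {
    stop("unannotatable protein: C2 motif not found ",
         "(amplicons are expected to start in C2)")
  }
  spans <- list(C2 = NULL, RHV = NULL, C3 = NULL, RC4 = NULL, C5 = NULL)
  for (r in c("C2", "C3", "RC4", "C5")) {
    if (placements[r, "present"]) {
      spans[[r]] <- c(placements[r, "start"], placements[r, "end"])
    }
  }
  # RHV: positional, between the end of C2 and the start of C3. With C3
  # present the window may be clipped at C3; in a truncated product (no
  # C3) a partial window is not called present.
  rhv_start <- spans$C2[2] + library$rhv_offset
  rhv_end <- rhv_start + library$rhv_length
  if (!is.null(spans$C3)) {
    rhv_end <- min(rhv_end, spans$C3[1])
    if (rhv_start < rhv_end) spans$RHV <- c(rhv_start, rhv_end)
  } else if (rhv_end <= n) {
    spans$RHV <- c(rhv_start, rhv_end)
  }

  order5 <- c("C2", "RHV", "C3", "RC4", "C5")
  segment_name <- function(a, b) {
    canonical <- c("C2-RHV", "RHV-C3", "C3-RC4", "RC4-C5")
    nm <- paste0(a, "-", b)
    if (nm %in% canonical) nm else nm  # non-adjacent gaps keep literal name
  }
  labels <- rep(NA_character_, n)
  present <- order5[!vapply(spans[order5], is.null, logical(1))]
  for (r in present) {
    s <- spans[[r]]
    labels[(s[1] + 1L):s[2]] <- r
  }
  # Fill gaps between (and around) present regions.
  full_next <- c(C2 = "RHV", RHV = "C3", C3 = "RC4", RC4 = "C5")
  pos <- 1L
  prev <- NULL
  for (r in present) {
    s <- spans[[r]]
    if (s[1] + 1L > pos) {
      seg <- if (is.null(prev)) paste0("pre-", r) else segment_name(prev, r)
      labels[pos:(s[1])] <- seg
    }
    pos <- s[2] + 1L
    prev <- r
  }
  if (pos <= n) {
    # trailing residues: extend C5 itself, else the canonical next segment
    tail_lab <- if (identical(prev, "C5")) "C5"
                else segment_name(prev, full_next[[prev]])
    labels[pos:n] <- tail_lab
  }
  structure(list(spans = spans, labels = labels, protein_length = n,
                 placements = placements),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  fmt <- vapply(names(x$spans), function(r) {
    s <- x$spans[[r]]
    if (is.null(s)) paste0(r, ": absent")
    else sprintf("%s: [%d,%d)", r, s[1], s[2])
  }, character(1))
  cat("region_map over", x$protein_length, "residues\n ",
      paste(fmt, collapse = "  "), "\n")
  invisible(x)
}

#' Region label of a residue position
#'
#' @param map A `region_map`.
#' @param position 0-based residue position(s).
#' @return Character vector of region/segment labels.
#' @export
region_of <- function(map, position) {
  stopifnot(inherits(map, "region_map"))
  map$labels[position + 1L]
}

#' Regions missing from a region map
#'
#' @param map A `region_map`.
#' @return Character vector, subset of `c("RHV", "C3", "RC4", "C5")` (C2 is
#'   required for annotation and so can never be reported missing).
#' @export
missing_regions <- function(map) {
  cand <- c("RHV", "C3", "RC4", "C5")
  cand[vapply(map$spans[cand], is.null, logical(1))]
}

# Total structure score used by detect_intron: sum of present motif scores
# minus a spacing penalty against the library's expected inter-motif gaps.
score_structure_protein <- function(residues, library, mat = NULL) {
  if (is.null(mat)) mat <- substitution_matrix(library$matrix_name)
  pl <- place_motifs(residues, library)
  rownames(pl) <- pl$region
  total <- sum(pl$score[pl$present])
  gaps <- c(C2.C3 = NA_real_, C3.RC4 = NA_real_, RC4.C5 = NA_real_)
  pair <- list(C2.C3 = c("C2", "C3"), C3.RC4 = c("C3", "RC4"),
               RC4.C5 = c("RC4", "C5"))
  for (g in names(pair)) {
    a <- pair[[g]][1]; b <- pair[[g]][2]
    if (pl[a, "present"] && pl[b, "present"]) {
      gaps[g] <- pl[b, "start"] - pl[a, "end"]
    }
  }
  dev <- abs(gaps - library$expected_gaps[names(gaps)])
  total <- total - library$width_penalty * sum(dev, na.rm = TRUE)
  list(total = total, placements = pl)
}
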