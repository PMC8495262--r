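# Gene structure on the amplicon and translation of the spliced CDS.
# Coordinates are 0-based, half-open everywhere internally; only reports
# use 1-based positions.

#' Construct a gene structure for a C2-C5 amplicon
#'
#' Describes the partial gene carried by one amplicon: part of exon 2, the
#' full second intron, and part of exon 3. Spans are 0-based half-open
#' intervals on the amplicon and must tile it contiguously in the order
#' exon2 < intron2 < exon3. `frame_offset` is the codon phase at the start
#' of exon 2 (0 when the amplicon begins on a codon boundary).
#'
#' @param exon2,intron2,exon3 Integer vectors `c(start, end)`.
#' @param frame_offset Codon phase at exon 2 start, in `0:2`.
#' @param sequence Optional amplicon sequence; when given, spans are checked
#'   against its length and the splice dinucleotides are recorded.
#' @return An object of class `gene_structure`.
#' @export
gene_structure <- function(exon2, intron2, exon3, frame_offset = 0L,
                           sequence = NULL) {
  spans <- list(exon2 = as.integer(exon2), intron2 = as.integer(intron2),
                exon3 = as.integer(exon3))
  for (nm in names(spans)) {
    s <- spans[[nm]]
    if (length(s) != 2L || s[1] < 0L || s[2] <= s[1]) {
      stop(nm, " span must be a non-empty 0-based half-open interval")
    }
  }
  if (spans$exon2[2] != spans$intron2[1] ||
      spans$intron2[2] != spans$exon3[1]) {
    stop("spans must be contiguous: exon2 < intron2 < exon3")
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be in 0:2")
  gs <- structure(
    c(spans, list(frame_offset = as.integer(frame_offset),
                  splice5_dinucleotide = NA_character_,
                  splice3_dinucleotide = NA_character_)),
    class = "gene_structure"
  )
  if (!is.null(sequence)) {
    if (spans$exon3[2] != nchar(sequence)) {
      stop("structure spans do not cover the sequence (",
           spans$exon3[2], " vs ", nchar(sequence), " bases)")
    }
    gs$splice5_dinucleotide <- substr(sequence, spans$intron2[1] + 1L,
                                      spans$intron2[1] + 2L)
    gs$splice3_dinucleotide <- substr(sequence, spans$intron2[2] - 1L,
                                      spans$intron2[2])
  }
  gs
}

#' @export
print.gene_structure <- function(x, ...) {
  w <- function(s) s[2] - s[1]
  cat(sprintf(
    "gene_structure: exon2 %d bp | intron2 %d bp (%s..%s) | exon3 %d bp, frame %d\n",
    w(x$exon2), w(x$intron2), x$splice5_dinucleotide,
    x$splice3_dinucleotide, w(x$exon3), x$frame_offset))
  invisible(x)
}

#' Intron width of a gene structure
#' @param structure A `gene_structure`.
#' @return Integer width in bp.
#' @export
intron_length <- function(structure) {
  structure$intron2[2] - structure$intron2[1]
}

# Extract a 0-based half-open span from a sequence string.
span_seq <- function(sequence, span) {
  substr(sequence, span[1] + 1L, span[2])
}

#' Spliced coding sequence of an amplicon
#'
#' Concatenates the exon 2 and exon 3 portions (removing the second intron).
#'
#' @param sequence Amplicon sequence.
#' @param structure Its `gene_structure`.
#' @return The spliced CDS string.
#' @export
splice_cds <- function(sequence, structure) {
  paste0(span_seq(sequence, structure$exon2),
         span_seq(sequence, structure$exon3))
}

# Codon table from the standard genetic code; codons containing N (or any
# ambiguity) translate to "X".
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate a DNA string
#'
#' Standard-code translation starting at `offset` (0-based). Trailing bases
#' that do not fill a codon are dropped. Codons containing `N` yield `X`;
#' stop codons yield `*` and are retained (use [translate_cds()] to stop at
#' the first stop codon).
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param offset 0-based offset of the first codon.
#' @return Amino-acid string, possibly containing `*` and `X`.
#' @export
translate_dna <- function(sequence, offset = 0L) {
  s <- substr(sequence, offset + 1L, nchar(sequence))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Deduce the protein encoded by an annotated amplicon
#'
#' Splices out the second intron, translates exon2+exon3 from the
#' structure's frame offset, and truncates at the first in-frame stop codon.
#'
#' @param sequence Amplicon sequence.
#' @param structure Its `gene_structure`.
#' @return An object of class `deduced_protein`: a list with `residues`
#'   (no internal stops), `stop_position` (0-based index of the first stop
#'   codon in the full translation, or `NA` if none is reached), and
#'   `novel_tail_length` (0 here; see [assess_splice_sites()] for
#'   retained-intron products).
#' @export
translate_cds <- function(sequence, structure) {
  full <- translate_dna(splice_cds(sequence, structure),
                        structure$frame_offset)
  stop_at <- regexpr("*", full, fixed = TRUE)
  if (stop_at > 0L) {
    residues <- substr(full, 1L, stop_at - 1L)
    stop_position <- as.integer(stop_at - 1L)
  } else {
    residues <- full
    stop_position <- NA_integer_
  }
  structure(list(residues = residues, stop_position = stop_position,
                 novel_tail_length = 0L),
            class = "deduced_protein")
}

#' @export
print.deduced_protein <- function(x, ...) {
  cat(sprintf("deduced_protein: %d residues%s\n", nchar(x$residues),
              if (!is.na(x$stop_position))
                sprintf(", stop codon at position %d", x$stop_position)
              else ""))
  invisible(x)
}
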