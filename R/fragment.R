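# Fragment sizing: amplicon lengths, gel band grouping at limited
# resolution, and capillary size-category binning.

#' Amplicon length from an annotated structure
#'
#' Sum of the exon2, intron2 and exon3 span widths; errors if the spans do
#' not cover the sequence, making this a consistency check as much as an
#' accessor.
#'
#' @param sequence Amplicon sequence.
#' @param structure Its `gene_structure`.
#' @return Integer length in bp.
#' @export
amplicon_length <- function(sequence, structure) {
  w <- (structure$exon2[2] - structure$exon2[1]) +
    (structure$intron2[2] - structure$intron2[1]) +
    (structure$exon3[2] - structure$exon3[1])
  if (w != nchar(sequence)) {
    stop("structure spans do not cover the sequence (", w, " vs ",
         nchar(sequence), " bases)")
  }
  w
}

#' Group fragment sizes into gel bands
#'
#' Single-linkage clustering of fragment sizes: two sizes end up in the
#' same band iff they are connected by a chain of gaps strictly below the
#' resolution. This models how adjacent smears merge on a gel, where
#' size differences under the resolution (about 60 bp on agarose for
#' these amplicons) cannot be reliably separated. With resolution 0 every
#' distinct size is its own band.
#'
#' @param sizes Positive integer fragment sizes (bp).
#' @param resolution_bp Gel resolution in bp (default 60).
#' @param allele_ids Optional vector parallel to `sizes`; when given, a
#'   band is flagged complex iff it contains fragments of two or more
#'   distinct alleles (co-migration). Without ids, any band with two or
#'   more member fragments is flagged.
#' @return An object of class `band_groups`: a list of bands, each with
#'   `members` (sizes), `allele_ids`, `representative` (integer median)
#'   and `is_complex`; bands are sorted by representative size. Empty
#'   input yields an empty list.
#' @export
group_bands <- function(sizes, resolution_bp = 60, allele_ids = NULL) {
  if (length(sizes) == 0L) {
    return(structure(list(), class = "band_groups"))
  }
  if (any(sizes <= 0)) stop("fragment sizes must be positive")
  if (resolution_bp < 0) stop("resolution_bp must be >= 0")
  if (!is.null(allele_ids) && length(allele_ids) != length(sizes)) {
    stop("allele_ids must parallel sizes")
  }
  ord <- order(sizes)
  s <- sizes[ord]
  ids <- if (is.null(allele_ids)) NULL else allele_ids[ord]
  breaks <- which(diff(s) >= resolution_bp)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(s))
  bands <- lapply(seq_along(starts), function(k) {
    sel <- starts[k]:ends[k]
    members <- s[sel]
    band_ids <- if (is.null(ids)) NULL else ids[sel]
    complex <- if (is.null(band_ids)) length(members) >= 2L
               else length(unique(band_ids)) >= 2L
    list(members = members, allele_ids = band_ids,
         representative = as.integer(round(stats::median(members))),
         is_complex = complex)
  })
  structure(bands, class = "band_groups")
}

#' @export
print.band_groups <- function(x, ...) {
  cat(length(x), "band(s)\n")
  for (b in x) {
    cat(sprintf("  ~%d bp: %d fragment(s)%s\n", b$representative,
                length(b$members), if (b$is_complex) " [complex]" else ""))
  }
  invisible(x)
}

#' Bin capillary fragment observations into size categories
#'
#' First-intron fragments are sized on a capillary sequencer to 1-bp
#' precision, so each exact integer size is its own category (sizes that
#' differ by a single bp remain distinct categories).
#'
#' @param observations Fragment table (see [read_fragment_table()]); only
#'   rows with assay `first-intron-capillary` are used when an `assay`
#'   column is present.
#' @return Named integer vector: category size -> fragment count. Empty
#'   input yields an empty vector.
#' @export
bin_size_categories <- function(observations) {
  sizes <- if (is.data.frame(observations)) {
    keep <- if ("assay" %in% names(observations)) {
      observations$assay == "first-intron-capillary"
    } else rep(TRUE, nrow(observations))
    observations$fragment_size[keep]
  } else {
    observations
  }
  if (length(sizes) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(sizes)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-sample allele detection summary
#'
#' Compares the alleles each sample truly carries (from a synthetic
#' family's truth table) with the bands observed for it, quantifying how
#' co-migration undercounts alleles.
#'
#' @param truth A `family_truth` object (see [simulate_family()]).
#' @param observed_bands Data frame of gel observations with columns
#'   `sample_id` and `fragment_size` (one row per band).
#' @return Data frame with one row per sample: `sample_id`,
#'   `alleles_carried` (distinct), `bands_seen`, `undercount`.
#' @export
summarize_detection <- function(truth, observed_bands) {
  samples <- truth$samples
  obs_ids <- unique(observed_bands$sample_id)
  unknown <- setdiff(obs_ids, names(samples))
  if (length(unknown) > 0L) {
    stop("observed bands for unknown sample(s): ",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(names(samples), function(sid) {
    carried <- length(unique(samples[[sid]]$alleles))
    seen <- sum(observed_bands$sample_id == sid)
    data.frame(sample_id = sid, alleles_carried = carried,
               bands_seen = seen, undercount = carried - seen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$undercount < 0)) {
    stop("more bands than carried alleles for sample(s): ",
         paste(out$sample_id[out$undercount < 0], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}
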