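#' Read an allele FASTA file
#'
#' Reads partial S-RNase amplicon sequences (typically spanning the C2 to C5
#' conserved regions and containing the full second intron) into an allele
#' table. The first whitespace-separated word of each header is taken as the
#' allele identifier; the remainder is scanned for `key=value` tokens, of
#' which `sample=`, `accession=` and `species=` are recognized (unknown keys
#' are ignored, which keeps headers derived from public databases usable).
#'
#' Sequences are uppercased and `U` is mapped to `T`. Only the alphabet
#' `A`, `C`, `G`, `T`, `N` is accepted.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A data frame with one row per record and columns `allele_id`,
#'   `sequence`, `sample_id`, `accession`, `species_tag` (missing metadata
#'   is `NA`). Row order follows file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">S1 accession=MG593769", "acgtacgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path)
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)

  parse_header <- function(h) {
    parts <- strsplit(trimws(h), "\\s+")[[1]]
    id <- parts[1]
    meta <- c(sample = NA_character_, accession = NA_character_,
              species = NA_character_)
    for (tok in parts[-1]) {
      if (grepl("=", tok, fixed = TRUE)) {
        kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
        if (kv[1] %in% names(meta)) meta[kv[1]] <- kv[2]
      }
    }
    c(allele_id = id, meta)
  }
  meta <- t(vapply(headers, parse_header, character(4)))

  records <- data.frame(
    allele_id = unname(meta[, "allele_id"]),
    sequence = unname(seqs),
    sample_id = unname(meta[, "sample"]),
    accession = unname(meta[, "accession"]),
    species_tag = unname(meta[, "species"]),
    stringsAsFactors = FALSE
  )
  validate_alleles(records)
  records
}

#' Validate an allele table
#'
#' Checks the invariants of the allele table: unique non-empty identifiers,
#' non-empty sequences, and an alphabet restricted to `A`, `C`, `G`, `T`,
#' `N`. Called by [read_fasta()]; exported so synthetic or hand-built tables
#' can be checked the same way.
#'
#' @param records Data frame with at least `allele_id` and `sequence`.
#' @return The input, invisibly, if valid. Errors otherwise.
#' @export
validate_alleles <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("allele_id", "sequence") %in% names(records)))
  dup <- records$allele_id[duplicated(records$allele_id)]
  if (length(dup) > 0L) {
    stop("duplicate allele_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(records$sequence))) {
    stop("empty sequence for allele: ",
         records$allele_id[!nzchar(records$sequence)][1])
  }
  bad <- regexpr("[^ACGTN]", records$sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("invalid character in sequence of allele ", records$allele_id[i],
         " at position ", bad[i], ": '",
         substr(records$sequence[i], bad[i], bad[i]), "'")
  }
  invisible(records)
}

#' Write an allele table to FASTA
#'
#' Inverse of [read_fasta()]: metadata columns are emitted as `key=value`
#' header tokens so that a write/read cycle reproduces the table exactly.
#'
#' @param records Allele table as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_alleles(records)
  tok <- function(key, val) {
    ifelse(is.na(val) | !nzchar(val), "", paste0(" ", key, "=", val))
  }
  sample_id <- if ("sample_id" %in% names(records)) records$sample_id else NA
  accession <- if ("accession" %in% names(records)) records$accession else NA
  species <- if ("species_tag" %in% names(records)) records$species_tag else NA
  headers <- paste0(">", records$allele_id, tok("sample", sample_id),
                    tok("accession", accession), tok("species", species))
  lines <- as.vector(rbind(headers, records$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fragment observation table
#'
#' Parses a TSV mirroring gel or capillary genotyping observations, with
#' columns `sample_id`, `size_bp` and `assay` (either `second-intron-gel` or
#' `first-intron-capillary`). Sizes must be positive integers; a
#' non-integer or non-positive size is reported with its line number.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `sample_id`, `fragment_size` (integer),
#'   `assay`. Empty tables (header only) yield zero rows.
#' @export
read_fragment_table <- function(path) {
  if (!file.exists(path)) stop("fragment table does not exist: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "size_bp", "assay")
  if (!all(need %in% names(tab))) {
    stop("fragment table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    return(data.frame(sample_id = character(), fragment_size = integer(),
                      assay = character(), stringsAsFactors = FALSE))
  }
  ok <- grepl("^[0-9]+$", tab$size_bp) & suppressWarnings(
    as.numeric(tab$size_bp)) > 0
  if (any(!ok)) {
    # +1 for the header line
    stop("invalid fragment size '", tab$size_bp[which(!ok)[1]],
         "' on line ", which(!ok)[1] + 1L, " of ", path)
  }
  data.frame(sample_id = tab$sample_id,
             fragment_size = as.integer(tab$size_bp),
             assay = tab$assay, stringsAsFactors = FALSE)
}

#' Write a rectangular report table as TSV
#'
#' Deterministic writer used for all tabular outputs: rows are sorted by the
#' first column, cells are written unquoted and UTF-8 encoded, so repeated
#' runs produce byte-identical files.
#'
#' @param table A data frame (may have zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) > 1L) {
    table <- table[order(table[[1]], method = "radix"), , drop = FALSE]
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Look up a scoring matrix by name
#'
#' Fetches one of the PAM/BLOSUM amino-acid substitution matrices shipped
#' with Biostrings (e.g. `"PAM250"`, `"PAM120"`, `"BLOSUM62"`).
#'
#' @param name Matrix name.
#' @return A numeric matrix with amino-acid row/column names.
#' @export
substitution_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(name = "PAM250") {
    if (!exists(name, envir = cache)) {
      e <- new.env()
      utils::data(list = name, package = "Biostrings", envir = e)
      assign(name, get(name, envir = e), envir = cache)
    }
    get(name, envir = cache)
  }
})
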