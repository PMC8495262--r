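# Distance-based phylogeny for trans-specificity support: site-coverage
# masking, gamma-corrected distances, neighbor joining, bootstrap.

#' Build an amino-acid alignment matrix from deduced proteins
#'
#' Equal-length proteins (the common case for amplicons without exonic
#' indels) are stacked directly. Unequal lengths are aligned with MAFFT
#' when it is on the PATH; alternatively a pre-computed aligned FASTA can
#' be supplied to the downstream functions directly.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @return Character matrix (rows = sequences, columns = sites) of class
#'   `aa_alignment`.
#' @export
align_proteins <- function(proteins) {
  stopifnot(length(proteins) >= 2L, !is.null(names(proteins)))
  lens <- nchar(proteins)
  if (length(unique(lens)) == 1L) {
    m <- do.call(rbind, strsplit(proteins, ""))
    rownames(m) <- names(proteins)
  } else {
    if (Sys.which("mafft") == "") {
      stop("proteins have unequal lengths and MAFFT is not available; ",
           "supply an externally aligned FASTA instead")
    }
    fin <- tempfile(fileext = ".fasta")
    fout <- tempfile(fileext = ".fasta")
    writeLines(as.vector(rbind(paste0(">", names(proteins)),
                               unname(proteins))), fin)
    system2("mafft", c("--auto", "--anysymbol", fin),
            stdout = fout, stderr = FALSE)
    aln <- Biostrings::readBStringSet(fout)
    m <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
    rownames(m) <- names(aln)
    m <- m[names(proteins), , drop = FALSE]
  }
  class(m) <- c("aa_alignment", class(m))
  m
}

#' Remove alignment columns with low site coverage
#'
#' Eliminates every column whose fraction of informative residues (not a
#' gap, not missing, not ambiguous) falls below the threshold; with the
#' default 0.95, fewer than 5 percent gaps/missing/ambiguous characters
#' are allowed at any retained position.
#'
#' @param alignment `aa_alignment` matrix (or plain character matrix).
#' @param threshold Minimum residue fraction per column, in \[0, 1\].
#' @return A list of class `masked_alignment`: `alignment` (masked
#'   matrix), `kept` (1-based original column indices), `threshold`.
#' @export
mask_low_coverage_columns <- function(alignment, threshold = 0.95) {
  stopifnot(is.matrix(alignment), threshold >= 0, threshold <= 1)
  uninformative <- c("-", ".", "X", "?", "*")
  cov <- colMeans(!matrix(alignment %in% uninformative,
                          nrow = nrow(alignment)))
  kept <- which(cov >= threshold)
  if (length(kept) == 0L) {
    stop("all alignment columns fall below the coverage threshold")
  }
  structure(list(alignment = alignment[, kept, drop = FALSE],
                 kept = kept, threshold = threshold),
            class = "masked_alignment")
}

#' Pairwise evolutionary distances from a masked alignment
#'
#' Three models: `p-distance` (mismatch proportion over columns where both
#' sequences carry residues), `poisson-gamma` (gamma-corrected Poisson
#' distance, d = a\[(1-p)^(-1/a) - 1\] with shape a), and `jtt-gamma`
#' (maximum-likelihood pairwise distances under the JTT substitution
#' matrix with gamma rate variation, 4 categories). Distances are in
#' amino-acid substitutions per site.
#'
#' @param masked A `masked_alignment` (or plain character matrix).
#' @param model Distance model.
#' @param gamma_shape Gamma shape parameter (default 0.8).
#' @param ceiling Distance assigned (with a warning) when the corrected
#'   transformation diverges (p >= 1).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
compute_distances <- function(masked,
                              model = c("p-distance", "poisson-gamma",
                                        "jtt-gamma"),
                              gamma_shape = 0.8, ceiling = 10) {
  model <- match.arg(model)
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  aln <- if (inherits(masked, "masked_alignment")) masked$alignment
         else masked
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  if (model == "jtt-gamma") {
    pd <- phangorn::phyDat(aln, type = "AA")
    d <- phangorn::dist.ml(pd, model = "JTT", k = 4L, shape = gamma_shape)
    m <- as.matrix(d)
    return(m[rownames(aln), rownames(aln)])
  }
  gapish <- c("-", ".", "X", "?", "*")
  m <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !(aln[i, ] %in% gapish) & !(aln[j, ] %in% gapish)
      if (!any(ok)) stop("no comparable columns between ",
                         rownames(aln)[i], " and ", rownames(aln)[j])
      p <- mean(aln[i, ok] != aln[j, ok])
      d <- if (model == "p-distance") p else {
        if (p >= 1) {
          warning("saturated pair ", rownames(aln)[i], "/",
                  rownames(aln)[j], "; distance set to ceiling")
          ceiling
        } else {
          min(gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1), ceiling)
        }
      }
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard NJ agglomeration on a symmetric distance matrix. Negative
#' branch-length estimates (a known NJ artifact) are clamped to zero with
#' the deficit transferred to the adjacent branch, preserving path
#' lengths between tips.
#'
#' @param distance_matrix Symmetric matrix with zero diagonal, at least 3
#'   taxa.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(distance_matrix) {
  m <- as.matrix(distance_matrix)
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  tree <- ape::nj(stats::as.dist(m))
  # Clamp negative branches (a known NJ artifact), moving each deficit to
  # one adjacent branch so tip-to-tip path lengths through the pair are
  # preserved; iteration is bounded, any residual negativity is truncated.
  for (iter in seq_len(2L * nrow(tree$edge))) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[which.min(tree$edge.length[neg])]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    adj <- which(tree$edge[, 1] == child)
    if (length(adj) == 0L) { # tip edge: pass the deficit to a sibling
      adj <- setdiff(which(tree$edge[, 1] == tree$edge[e, 1]), e)
    }
    adj <- adj[which.max(tree$edge.length[adj])]
    tree$edge.length[adj] <- tree$edge.length[adj] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate under the same distance model, and reports for each internal
#' branch of the original tree the percentage of replicates containing
#' that bipartition. Fully reproducible given the seed.
#'
#' @param masked A `masked_alignment`.
#' @param model,gamma_shape Passed to [compute_distances()].
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed for the resampling.
#' @return The NJ tree of the full alignment, with `node.label` holding
#'   the support percentages (root label empty).
#' @export
bootstrap_support <- function(masked, model = "jtt-gamma",
                              gamma_shape = 0.8, n_replicates = 100L,
                              seed = 1L) {
  stopifnot(inherits(masked, "masked_alignment"), n_replicates >= 1L)
  aln <- masked$alignment
  base <- nj_tree(compute_distances(masked, model = model,
                                    gamma_shape = gamma_shape))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  boots <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    boots[[r]] <- nj_tree(compute_distances(
      aln[, cols, drop = FALSE], model = model, gamma_shape = gamma_shape))
  }
  counts <- ape::prop.clades(base, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_replicates, 1)
  labels <- as.character(support)
  labels[1] <- ""  # root of the unrooted representation
  base$node.label <- labels
  base
}

#' Write a tree in Newick format
#'
#' Branch lengths are always written; bootstrap supports (if present)
#' appear as internal node labels. The output round-trips through
#' [ape::read.tree()].
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
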