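# Shared fixtures, built once per test run and cached, plus independent
# brute-force oracles used to cross-check the implementation.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The standard seeded 23-allele family (20 base + 3 mutant derivatives,
# plus trans-specific duplicates in a second species).
syn_family <- function() {
  .cached("family", function() simulate_family(family_config(seed = 1)))
}

syn_annotations <- function() {
  .cached("annotations", function() annotate_alleles(syn_family()$records))
}

syn_matrices <- function() {
  .cached("matrices", function() {
    build_identity_matrices(syn_family()$records, syn_annotations())
  })
}

# Path of the deposited 23-allele FASTA (GenBank records); only present
# when a copy has been placed under inst/extdata/deposited/.
deposited_fasta_path <- function() {
  system.file("extdata", "deposited", "plau_srnase.fasta",
              package = "srnase")
}

# ---- independent oracles ------------------------------------------------

# Brute-force single-linkage grouping: connected components of the graph
# whose edges join size pairs closer than the resolution.
brute_single_linkage <- function(sizes, resolution) {
  n <- length(sizes)
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(sizes[i] - sizes[j]) < resolution) {
        old <- comp[j]
        comp[comp == old] <- comp[i]
      }
    }
  }
  unname(lapply(split(sizes, comp), sort))
}

# Exhaustive global alignment over all monotone matchings with affine gap
# costs (each maximal unmatched run costs open + len * ext). Returns the
# optimal score and the set of percent identities (matches over columns)
# attained by optimal matchings.
brute_align_best <- function(a, b, match = 2, mismatch = -1,
                             open = 10, ext = 0.2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  gapcost <- function(k) if (k > 0) open + ext * k else 0
  best <- -Inf
  idents <- numeric(0)
  rec <- function(i, j, score, pairs, matches) {
    # close the alignment here
    total <- score - gapcost(n - i + 1) - gapcost(m - j + 1)
    cols <- pairs + (n - pairs) + (m - pairs)
    id <- 100 * matches / cols
    if (total > best + 1e-9) {
      best <<- total
      idents <<- id
    } else if (abs(total - best) <= 1e-9) {
      idents <<- unique(c(idents, id))
    }
    # or match one more pair (k, l)
    if (i <= n && j <= m) {
      for (k in i:n) {
        for (l in j:m) {
          s <- score - gapcost(k - i) - gapcost(l - j) +
            (if (av[k] == bv[l]) match else mismatch)
          rec(k + 1, l + 1, s, pairs + 1,
              matches + (av[k] == bv[l]))
        }
      }
    }
  }
  rec(1, 1, 0, 0, 0)
  list(score = best, identities = idents)
}

# Random additive distance matrix from a random unrooted tree with
# strictly positive branch lengths; returns the tree and its tip-to-tip
# path-length matrix.
random_additive_case <- function(n_taxa) {
  tree <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 1)
  list(tree = tree, d = stats::cophenetic(tree))
}
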