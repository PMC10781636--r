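# Shared helpers: random trees and independent brute-force oracles.

random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n)
  phy$node.label <- NULL
  read_newick(write_newick(phy))
}

# MRCA oracle: least node (fewest descendant leaves) whose leaf set contains
# all query leaves.
mrca_oracle <- function(idx, leaves) {
  cand <- which(vapply(seq_along(idx$leafset), function(v)
    all(leaves %in% idx$leafset[[v]]), TRUE))
  sizes <- vapply(cand, function(v) length(idx$leafset[[v]]), 0L)
  idx$labels[cand[which.min(sizes)]]
}

# Species-overlap oracle: recompute duplication labels with an explicit
# pairwise species-set intersection over leaf descendants.
overlap_oracle <- function(idx, species_map) {
  n <- idx$ntip + idx$nnode
  out <- character(n)
  for (v in seq_len(n)) {
    if (v <= idx$ntip) { out[v] <- "leaf"; next }
    kids <- idx$children[[v]]
    sets <- lapply(kids, function(k) unique(species_map[idx$leafset[[k]]]))
    dup <- FALSE
    for (i in seq_along(sets)) for (j in seq_along(sets))
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0) dup <- TRUE
    out[v] <- if (dup) "duplication" else "speciation"
  }
  out
}

# Exhaustive hypergeometric enrichment oracle: enumerate every selection of
# n_selected items and count those with at least k class members.
fisher_oracle <- function(n_total, n_class, n_selected, k) {
  sel <- utils::combn(n_total, n_selected)
  in_class <- colSums(sel <= n_class)   # items 1..n_class form the class
  mean(in_class >= k)
}

# Tiny IUPAC matcher used as the scanning oracle.
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                   Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                   K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                   D = c("A", "G", "T"), H = c("A", "C", "T"),
                   V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

scan_oracle <- function(seq, word) {
  sc <- strsplit(seq, "")[[1]]
  wc <- strsplit(word, "")[[1]]
  L <- length(sc); w <- length(wc)
  hits <- integer(0)
  if (L >= w) for (p in 1:(L - w + 1)) {
    ok <- all(vapply(seq_len(w), function(j)
      sc[p + j - 1] %in% iupac_sets[[wc[j]]], TRUE))
    if (ok) hits <- c(hits, p)
  }
  hits
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Presence matrix over random carriers on a tree.
random_presence <- function(phy, n_clades = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tips <- phy$tip.label
  states <- matrix("absent", length(tips), n_clades,
                   dimnames = list(tips, paste0("fam", seq_len(n_clades))))
  for (j in seq_len(n_clades)) {
    k <- sample(seq_along(tips), 1)
    carriers <- sample(tips, k)
    st <- sample(c("intact", "pseudogene"), k, replace = TRUE,
                 prob = c(0.85, 0.15))
    states[carriers, j] <- st
    if (all(states[, j] != "intact"))
      states[carriers[1], j] <- "intact"
  }
  presence_matrix(states)
}

pm_equal <- function(a, b) {
  cl <- sort(colnames(a$states))
  identical(a$states[, cl, drop = FALSE][order(rownames(a$states)), , drop = FALSE],
            b$states[, cl, drop = FALSE][order(rownames(b$states)), , drop = FALSE])
}
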