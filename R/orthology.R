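#' Label gene-tree nodes as speciation or duplication by species overlap
#'
#' An internal node is a duplication if the species sets of at least two of
#' its children intersect, otherwise a speciation (the pairwise rule, applied
#' to every pair of children so polytomies are handled conservatively).
#'
#' @param gene_tree Rooted `phylo` whose tips are gene identifiers.
#' @param species_map Named character vector mapping every gene id to a
#'   species id.
#' @return A `tree_index` for the gene tree with extra elements
#'   `species_map`, `species_set` (per node) and `event` (`"leaf"`,
#'   `"speciation"` or `"duplication"` per node).
#' @examples
#' gt <- read_newick("((g1,g2),g3);")
#' label_duplications(gt, c(g1 = "X", g2 = "Y", g3 = "Z"))$event
#' @export
label_duplications <- function(gene_tree, species_map) {
  idx <- tree_index(gene_tree)
  tips <- idx$labels[seq_len(idx$ntip)]
  unmapped <- setdiff(tips, names(species_map))
  if (length(unmapped))
    stop("unmapped gene leaves: ", paste(unmapped, collapse = ", "))
  n <- idx$ntip + idx$nnode
  species_set <- vector("list", n)
  event <- character(n)
  for (v in idx$postorder) {
    if (v <= idx$ntip) {
      species_set[[v]] <- unname(species_map[idx$labels[v]])
      event[v] <- "leaf"
    } else {
      kids <- idx$children[[v]]
      sets <- lapply(kids, function(k) species_set[[k]])
      dup <- FALSE
      if (length(sets) > 1L)
        for (i in seq_len(length(sets) - 1L))
          for (j in (i + 1L):length(sets))
            if (length(intersect(sets[[i]], sets[[j]]))) { dup <- TRUE; break }
      event[v] <- if (dup) "duplication" else "speciation"
      species_set[[v]] <- unique(unlist(sets))
    }
  }
  idx$species_map <- species_map
  idx$species_set <- species_set
  idx$event <- event
  class(idx) <- c("labelled_gene_tree", class(idx))
  idx
}

# Does duplication node v split lineages at the given level?
#  - clade level: yes unless the node's species span lies within a single
#    species or a single taxon group;
#  - subclade level: yes unless the span is a single species.
.dup_splits <- function(lab, v, level, group_of) {
  sp <- lab$species_set[[v]]
  if (length(sp) <= 1L) return(FALSE)
  if (level == "subclade") return(TRUE)
  g <- unique(group_of[sp])
  !(length(g) == 1L && !anyNA(g))
}

#' Cut a labelled gene tree into ortholog clades
#'
#' Ortholog clades are the connected components obtained by cutting the gene
#' tree at every duplication node that separates lineages at the requested
#' level. Duplications confined to a
#' single species never split (they are within-species copies). At
#' `level = "clade"` duplications confined to a single taxon group (for
#' example an order or class supplied via `taxon_groups`) do not split
#' either; at `level = "subclade"` they do, which is how subclades that arose
#' at the base of a taxon group are separated.
#'
#' @param labelled A tree from [label_duplications()].
#' @param level `"clade"` or `"subclade"`.
#' @param taxon_groups Named character vector mapping species id to taxon
#'   group; species without an entry form their own group.
#' @param labels Optional named character vector mapping one representative
#'   gene id per clade to the label to use; unmatched clades are labelled
#'   `clade_01`, `clade_02`, ... in tree order.
#' @return A data.frame of class `clade_assignment` with columns `gene`,
#'   `species`, `clade`.
#' @export
extract_clades <- function(labelled, level = c("clade", "subclade"),
                           taxon_groups = NULL, labels = NULL) {
  if (!inherits(labelled, "labelled_gene_tree"))
    stop("`labelled` must come from label_duplications()")
  level <- match.arg(level)
  lab <- labelled
  all_sp <- unique(unname(lab$species_map))
  group_of <- stats::setNames(all_sp, all_sp)      # default: own group
  if (!is.null(taxon_groups)) {
    known <- intersect(names(taxon_groups), all_sp)
    group_of[known] <- taxon_groups[known]
  }
  n <- lab$ntip + lab$nnode
  # Clades are the connected components of the gene tree after cutting at
  # every splitting duplication node: each child of such a node starts a new
  # component, and every other node inherits its parent's component (a
  # component need not be a clean subtree - the lineage that persists around
  # a nested duplication stays one clade).
  splits <- vapply(seq_len(n), function(v)
    v > lab$ntip && lab$event[v] == "duplication" &&
      .dup_splits(lab, v, level, group_of), TRUE)
  comp <- integer(n)
  ncomp <- 1L
  comp[lab$root] <- 1L
  for (v in lab$preorder) {
    if (v == lab$root) next
    p <- lab$parent[v]
    if (splits[p]) { ncomp <- ncomp + 1L; comp[v] <- ncomp }
    else comp[v] <- comp[p]
  }
  leaf_comp <- comp[seq_len(lab$ntip)]
  groups <- split(lab$labels[seq_len(lab$ntip)], leaf_comp)
  groups <- groups[order(vapply(groups, function(g)
    min(match(g, lab$labels)), 1L))]           # stable tree order
  names(groups) <- NULL
  clade_names <- sprintf("clade_%02d", seq_along(groups))
  if (!is.null(labels)) {
    for (i in seq_along(groups)) {
      hit <- intersect(names(labels), groups[[i]])
      if (length(hit)) clade_names[i] <- unname(labels[hit[1L]])
    }
  }
  out <- do.call(rbind, lapply(seq_along(groups), function(i)
    data.frame(gene = groups[[i]],
               species = unname(lab$species_map[groups[[i]]]),
               clade = clade_names[i], row.names = NULL)))
  class(out) <- c("clade_assignment", class(out))
  out
}

#' Count clades with intact members per species
#'
#' @param x A [presence_matrix()] or a `clade_assignment` from
#'   [extract_clades()].
#' @param count_pseudogenes Include pseudogene-only clades in the count?
#'   For a `clade_assignment`, pseudogene membership is taken from the
#'   optional `pseudogene` logical column (all intact when absent).
#' @return Named integer vector, one entry per species.
#' @export
clades_per_species <- function(x, count_pseudogenes = FALSE) {
  if (inherits(x, "presence_matrix")) {
    keep <- if (count_pseudogenes) x$states != "absent" else x$states == "intact"
    return(stats::setNames(as.integer(rowSums(keep)), x$species))
  }
  if (inherits(x, "clade_assignment")) {
    d <- x
    if (!count_pseudogenes && !is.null(d$pseudogene)) d <- d[!d$pseudogene, ]
    tab <- tapply(d$clade, d$species, function(cl) length(unique(cl)))
    out <- stats::setNames(as.integer(tab), names(tab))
    missing <- setdiff(unique(x$species), names(out))
    c(out, stats::setNames(integer(length(missing)), missing))
  } else stop("unsupported input")
}
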