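#' Read a rooted tree from Newick text
#'
#' Thin wrapper around [ape::read.tree()] that validates the input for use as
#' a species tree or gene tree: the tree is kept rooted as given (no
#' rerooting), leaf labels must be unique, and internal nodes without a label
#' receive a stable auto-generated one (`node_<i>`, numbered in ape's node
#' order) so that every branch can be addressed by the label of its child
#' node.
#'
#' @param text Newick string (with optional support values / internal labels
#'   and branch lengths). Exactly one of `text` or `file` must be given.
#' @param file Path to a Newick file.
#' @return An object of class `phylo` with unique tip and node labels.
#' @examples
#' tr <- read_newick("((A,B)ab,C)root;")
#' tr$tip.label
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input")
  no <- sum(strsplit(text, "")[[1]] == "(")
  nc <- sum(strsplit(text, "")[[1]] == ")")
  if (no != nc)
    stop(sprintf("unbalanced parentheses in Newick input (%d '(' vs %d ')')",
                 no, nc))
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: input could not be parsed")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  phy <- .fill_node_labels(phy)
  phy
}

#' Write a tree to Newick text
#'
#' @param phy A `phylo` tree.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(phy, file = NULL) {
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Ensure every internal node carries a unique non-empty label.
.fill_node_labels <- function(phy) {
  nn <- phy$Nnode
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", nn)
  lab[is.na(lab)] <- ""
  auto <- paste0("node_", seq_len(nn))
  lab[!nzchar(lab)] <- auto[!nzchar(lab)]
  while (any(d <- duplicated(c(phy$tip.label, lab))[-seq_along(phy$tip.label)]))
    lab[d] <- paste0(lab[d], "_")
  phy$node.label <- lab
  phy
}

#' Build a traversal index for a rooted tree
#'
#' Precomputes parent/child links, postorder, per-node leaf sets and a
#' label-to-node lookup. Most package functions accept either a `phylo` tree
#' or an index built from one; building the index once is cheaper when many
#' queries are made against the same tree.
#'
#' @param phy A `phylo` tree (polytomies allowed).
#' @return A list of class `tree_index` with elements `phy`, `ntip`, `nnode`,
#'   `labels` (tip then node labels, indexed by ape node number), `parent`,
#'   `children`, `postorder`, `leafset` (character leaf labels per node) and
#'   `node_of` (named integer lookup).
#' @export
tree_index <- function(phy) {
  if (inherits(phy, "tree_index")) return(phy)
  stopifnot(inherits(phy, "phylo"))
  phy <- .fill_node_labels(phy)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  labels <- c(phy$tip.label, phy$node.label)
  parent <- integer(n)          # 0 for the root
  children <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  root <- if (ntip == 1L) ntip + 1L else setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  # postorder: children before parents
  po <- integer(0)
  stack <- root; seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  po <- rev(seen)
  leafset <- vector("list", n)
  for (v in po) {
    if (v <= ntip) leafset[[v]] <- labels[v]
    else leafset[[v]] <- unlist(lapply(children[[v]], function(c) leafset[[c]]),
                                use.names = FALSE)
  }
  node_of <- stats::setNames(seq_len(n), labels)
  structure(list(phy = phy, ntip = ntip, nnode = nnode, labels = labels,
                 parent = parent, children = children, root = root,
                 postorder = po, preorder = seen, leafset = leafset,
                 node_of = node_of),
            class = "tree_index")
}

# Resolve labels (or node numbers) to node numbers, with checking.
.node_id <- function(idx, x) {
  if (is.numeric(x)) return(as.integer(x))
  i <- idx$node_of[x]
  if (anyNA(i))
    stop("unknown node/leaf label: ", paste(x[is.na(i)], collapse = ", "))
  unname(i)
}

# Path from node v up to the root (inclusive), as node numbers.
.path_to_root <- function(idx, v) {
  out <- v
  while (idx$parent[v] != 0L) {
    v <- idx$parent[v]
    out <- c(out, v)
  }
  out
}

#' Most recent common ancestor of a set of leaves
#'
#' Returns the least node of the rooted tree whose descendant leaf set
#' contains all of `leaves`. A single leaf is its own MRCA.
#'
#' @param tree A `phylo` tree or a [tree_index()].
#' @param leaves Character vector of leaf labels (non-empty).
#' @return The label of the MRCA node.
#' @examples
#' mrca(read_newick("((A,B)ab,C)r;"), c("A", "B"))
#' @export
mrca <- function(tree, leaves) {
  idx <- tree_index(tree)
  if (!length(leaves)) stop("empty leaf set")
  ids <- .node_id(idx, leaves)
  if (any(ids > idx$ntip))
    stop("not a leaf: ", paste(leaves[ids > idx$ntip], collapse = ", "))
  anc <- .path_to_root(idx, ids[1L])
  for (v in ids[-1L]) anc <- intersect(anc, .path_to_root(idx, v))
  # intersect preserves order of the first path: first element is the least
  idx$labels[anc[1L]]
}

# Internal: MRCA returning a node number, accepting node numbers as input
# (works for internal nodes too, via path intersection).
.mrca_nodes <- function(idx, nodes) {
  nodes <- unique(nodes)
  anc <- .path_to_root(idx, nodes[1L])
  for (v in nodes[-1L]) anc <- intersect(anc, .path_to_root(idx, v))
  anc[1L]
}

# Is node a an ancestor of (or equal to) node b?
.is_ancestor <- function(idx, a, b) {
  while (b != 0L) {
    if (b == a) return(TRUE)
    b <- idx$parent[b]
  }
  FALSE
}

#' Presence/absence/pseudogene matrix
#'
#' Construct and validate a species-by-clade state matrix. States are
#' `"absent"`, `"intact"` or `"pseudogene"`; an optional copy-number matrix
#' records how many copies a species carries (>= 1 wherever the state is not
#' absent).
#'
#' @param states Character matrix (rows = species, columns = clade labels)
#'   with entries in `c("absent", "intact", "pseudogene")`.
#' @param copies Optional integer matrix of the same shape; defaults to 1 for
#'   every non-absent cell.
#' @param species_tree Optional `phylo`/[tree_index()]; when given, every row
#'   name must be a leaf of the tree.
#' @return A list of class `presence_matrix` with elements `states`, `copies`,
#'   `species`, `clades`.
#' @export
presence_matrix <- function(states, copies = NULL, species_tree = NULL) {
  stopifnot(is.matrix(states), !is.null(rownames(states)),
            ncol(states) == 0 || !is.null(colnames(states)))
  bad <- setdiff(unique(as.vector(states)), c("absent", "intact", "pseudogene"))
  if (length(bad)) stop("unknown state token: ", paste(bad, collapse = ", "))
  if (is.null(copies)) {
    copies <- matrix(0L, nrow(states), ncol(states), dimnames = dimnames(states))
    copies[states != "absent"] <- 1L
  }
  stopifnot(all(dim(copies) == dim(states)))
  if (any(copies[states != "absent"] < 1L))
    stop("copy number must be >= 1 where a clade is present")
  if (!is.null(species_tree)) {
    idx <- tree_index(species_tree)
    unknown <- setdiff(rownames(states), idx$leafset[[idx$root]])
    if (length(unknown))
      stop("species absent from tree: ", paste(unknown, collapse = ", "))
  }
  structure(list(states = states, copies = copies,
                 species = rownames(states), clades = colnames(states)),
            class = "presence_matrix")
}

#' Read a presence matrix from TSV
#'
#' The dialect has a header row of clade labels and one row per species.
#' Cells are `0` (absent), `1` (intact), `P` (pseudogene), or `1:n` / `P:n`
#' for copy number `n`.
#'
#' @param file Path to a TSV file, or a literal TSV string containing a
#'   newline.
#' @param species_tree Optional tree used to validate species names.
#' @return A [presence_matrix()].
#' @export
read_presence_matrix <- function(file, species_tree = NULL) {
  txt <- if (grepl("\n", file)) file else paste(readLines(file), collapse = "\n")
  df <- utils::read.table(text = txt, header = TRUE, sep = "\t",
                          row.names = 1, check.names = FALSE,
                          colClasses = "character")
  tok <- as.matrix(df)
  states <- matrix("absent", nrow(tok), ncol(tok), dimnames = dimnames(tok))
  copies <- matrix(0L, nrow(tok), ncol(tok), dimnames = dimnames(tok))
  for (i in seq_along(tok)) {
    parts <- strsplit(tok[i], ":", fixed = TRUE)[[1]]
    s <- parts[1]
    n <- if (length(parts) > 1L) as.integer(parts[2]) else NA_integer_
    if (length(parts) > 2L || (length(parts) == 2L && (is.na(n) || n < 1L)))
      stop("unknown state token: ", tok[i])
    if (s == "0") {
      if (length(parts) > 1L) stop("unknown state token: ", tok[i])
    } else if (s == "1") {
      states[i] <- "intact"; copies[i] <- if (is.na(n)) 1L else n
    } else if (s == "P") {
      states[i] <- "pseudogene"; copies[i] <- if (is.na(n)) 1L else n
    } else stop("unknown state token: ", tok[i])
  }
  presence_matrix(states, copies, species_tree)
}

#' Write a presence matrix to TSV
#'
#' @param pm A [presence_matrix()].
#' @param file Optional output path; when `NULL` the TSV text is returned.
#' @export
write_presence_matrix <- function(pm, file = NULL) {
  tok <- matrix("0", length(pm$species), length(pm$clades),
                dimnames = list(pm$species, pm$clades))
  tok[pm$states == "intact"] <- "1"
  tok[pm$states == "pseudogene"] <- "P"
  extra <- pm$states != "absent" & pm$copies > 1L
  tok[extra] <- paste0(tok[extra], ":", pm$copies[extra])
  lines <- c(paste(c("species", pm$clades), collapse = "\t"),
             vapply(seq_along(pm$species), function(i)
               paste(c(pm$species[i], tok[i, ]), collapse = "\t"), ""))
  if (is.null(file)) return(paste(lines, collapse = "\n"))
  writeLines(lines, file)
  invisible(file)
}

# Species carrying a clade (any non-absent state).
.carriers <- function(pm, clade) {
  pm$species[pm$states[, clade] != "absent"]
}

#' Gene model with ordered exons
#'
#' Exon coordinates are 0-based, half-open, listed in transcription order
#' (for minus-strand genes this is the reverse of genomic order). Exons must
#' not overlap.
#'
#' @param gene_id,species,scaffold Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) in transcription order.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, species, scaffold, strand, exons) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2,
            nrow(exons) >= 1)
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  g <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(g) > 1 && any(g[-1, 1] < g[-nrow(g), 2]))
    stop("overlapping exons")
  ord <- order(exons[, 1], decreasing = (strand == "-"))
  if (!identical(ord, seq_len(nrow(exons))))
    stop("exons not sorted in transcription order")
  structure(list(gene_id = gene_id, species = species, scaffold = scaffold,
                 strand = strand, exons = exons),
            class = "gene_model")
}

#' Read gene models from a BED-like TSV
#'
#' Six columns: scaffold, start, end, strand, gene id, species. Consecutive
#' rows with the same gene id are collected as that gene's exons.
#'
#' @param file Path or literal TSV text (with a newline).
#' @return A list of [gene_model()] objects, named by gene id.
#' @export
read_gene_models <- function(file) {
  txt <- if (grepl("\n", file)) file else paste(readLines(file), collapse = "\n")
  df <- utils::read.table(text = txt, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "start", "end",
                                        "strand", "gene", "species"),
                          colClasses = c("character", "integer", "integer",
                                        "character", "character", "character"))
  out <- lapply(split(df, df$gene), function(d) {
    ex <- as.matrix(d[, c("start", "end")])
    if (d$strand[1] == "-") ex <- ex[order(ex[, 1], decreasing = TRUE), , drop = FALSE]
    else ex <- ex[order(ex[, 1]), , drop = FALSE]
    dimnames(ex) <- NULL
    gene_model(d$gene[1], d$species[1], d$scaffold[1], d$strand[1], ex)
  })
  out[unique(df$gene)]
}
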