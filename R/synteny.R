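# Tandem clusters, conserved adjacencies and ancestral gene orders.
#
# A gene order is one scaffold's coordinate-sorted gene symbols with a
# family-membership flag. Adjacencies are unordered symbol pairs (strand and
# orientation are ignored); the family cluster can be collapsed to a single
# token so that flanking adjacencies are comparable across species whose
# cluster content differs. Each adjacency is treated as a binary character
# and reconstructed by Dollo parsimony (single gain at the MRCA of the
# carrier species, minimal losses below).

#' Build a gene-order record
#'
#' @param species,scaffold Identifiers.
#' @param symbols Character vector of gene symbols in coordinate order
#'   (unique within the scaffold).
#' @param strand Optional strand vector (defaults to `"+"`).
#' @param family Logical vector flagging gene-family members; by default
#'   symbols matching `family_regex`.
#' @param family_regex Used when `family` is `NULL`.
#' @return A data.frame of class `gene_order` with columns `species`,
#'   `scaffold`, `symbol`, `strand`, `family`.
#' @export
gene_order <- function(species, scaffold, symbols, strand = NULL,
                       family = NULL, family_regex = "^TAS1R") {
  if (anyDuplicated(symbols))
    stop("duplicate symbols within a scaffold record: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  if (is.null(strand)) strand <- rep("+", length(symbols))
  if (is.null(family)) family <- grepl(family_regex, symbols)
  out <- data.frame(species = species, scaffold = scaffold, symbol = symbols,
                    strand = strand, family = family)
  class(out) <- c("gene_order", class(out))
  out
}

#' Read gene orders from a BED-like TSV
#'
#' Columns: scaffold, start, end, strand, symbol, species. Orders are
#' coordinate-sorted within each (species, scaffold).
#'
#' @param file Path or literal TSV text (with a newline).
#' @inheritParams gene_order
#' @return A list of `gene_order` records, one per (species, scaffold).
#' @export
read_gene_orders <- function(file, family_regex = "^TAS1R") {
  txt <- if (grepl("\n", file)) file else paste(readLines(file), collapse = "\n")
  df <- utils::read.table(text = txt, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "start", "end", "strand",
                                        "symbol", "species"))
  parts <- split(df, paste(df$species, df$scaffold, sep = "\r"))
  out <- lapply(parts, function(d) {
    d <- d[order(d$start), ]
    gene_order(d$species[1], d$scaffold[1], d$symbol, d$strand,
               family_regex = family_regex)
  })
  names(out) <- vapply(out, function(o) paste(o$species[1], o$scaffold[1],
                                              sep = ":"), "")
  out
}

#' Detect tandem clusters of family members
#'
#' Maximal runs of family genes separated by at most `max_intervening`
#' non-family genes.
#'
#' @param order A `gene_order`.
#' @param max_intervening Allowed non-family genes between cluster members.
#' @return List of character vectors (family symbols per cluster, in order).
#' @export
detect_clusters <- function(order, max_intervening = 0) {
  fam_pos <- which(order$family)
  if (!length(fam_pos)) return(list())
  clusters <- list()
  current <- fam_pos[1]
  for (p in fam_pos[-1]) {
    if (p - current[length(current)] - 1L <= max_intervening)
      current <- c(current, p)
    else {
      clusters[[length(clusters) + 1L]] <- order$symbol[current]
      current <- p
    }
  }
  clusters[[length(clusters) + 1L]] <- order$symbol[current]
  clusters
}

# Symbol sequence of one order with the family cluster(s) collapsed to a
# single token.
.collapsed_symbols <- function(order, token = "FAMILY_CLUSTER") {
  sy <- order$symbol
  fam <- order$family
  out <- character(0)
  i <- 1L
  while (i <= length(sy)) {
    if (fam[i]) {
      while (i <= length(sy) && fam[i]) i <- i + 1L
      out <- c(out, token)
    } else {
      out <- c(out, sy[i])
      i <- i + 1L
    }
  }
  out
}

# Unordered adjacency pairs of one order (optionally collapsed).
.order_pairs <- function(order, collapse_family = FALSE,
                         token = "FAMILY_CLUSTER") {
  sy <- if (collapse_family) .collapsed_symbols(order, token) else order$symbol
  if (length(sy) < 2L) return(character(0))
  a <- sy[-length(sy)]; b <- sy[-1]
  unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

.pair_key <- function(pair) paste(pmin(pair[1], pair[2]),
                                  pmax(pair[1], pair[2]), sep = "|")

#' Presence of a gene adjacency across species
#'
#' @param orders List of `gene_order` records (possibly several scaffolds per
#'   species).
#' @param pair Character vector of two symbols; the family-cluster token
#'   (`"FAMILY_CLUSTER"`) may be used when `collapse_family = TRUE`.
#' @param collapse_family Collapse runs of family genes to a single token
#'   before testing adjacency.
#' @return Named logical vector, one entry per species present in `orders`.
#' @export
adjacency_presence <- function(orders, pair, collapse_family = FALSE) {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  key <- .pair_key(pair)
  species <- unique(vapply(orders, function(o) o$species[1], ""))
  out <- stats::setNames(rep(FALSE, length(species)), species)
  for (o in orders) {
    if (key %in% .order_pairs(o, collapse_family)) out[o$species[1]] <- TRUE
  }
  out
}

#' Dollo reconstruction of ancestral adjacencies
#'
#' Each adjacency observed in at least one species is treated as a binary
#' character gained once (at the MRCA of its carrier species) and lost below;
#' it is present at a node iff the node lies on the spanning subtree
#' connecting the gain node to the carriers.
#'
#' @param species_tree `phylo` or [tree_index()].
#' @param orders List of `gene_order` records.
#' @param collapse_family Collapse the family cluster before computing
#'   adjacencies.
#' @return A list of class `adjacency_set`: `node_adjacencies` (per species
#'   tree node label, a character matrix with columns `a`, `b`) and
#'   `adjacency_species` (list: pair key -> carrier species).
#' @export
ancestral_adjacencies <- function(species_tree, orders, collapse_family = FALSE) {
  idx <- tree_index(species_tree)
  carriers <- list()
  for (o in orders) {
    sp <- o$species[1]
    for (k in .order_pairs(o, collapse_family))
      carriers[[k]] <- unique(c(carriers[[k]], sp))
  }
  node_adj <- stats::setNames(
    rep(list(character(0)), idx$ntip + idx$nnode), idx$labels)
  for (k in names(carriers)) {
    sp <- intersect(carriers[[k]], idx$labels[seq_len(idx$ntip)])
    if (!length(sp)) next
    origin <- .mrca_nodes(idx, .node_id(idx, sp))
    for (v in .dollo_present(idx, origin, sp))
      node_adj[[idx$labels[v]]] <- c(node_adj[[idx$labels[v]]], k)
  }
  node_adj <- lapply(node_adj, function(ks) {
    ks <- sort(ks)
    m <- do.call(rbind, strsplit(ks, "|", fixed = TRUE))
    if (is.null(m)) m <- matrix(character(0), 0, 2)
    colnames(m) <- c("a", "b")
    m
  })
  structure(list(node_adjacencies = node_adj, adjacency_species = carriers),
            class = "adjacency_set")
}

#' Assemble linear gene orders from an adjacency set
#'
#' Builds the graph whose edges are the adjacencies at one node and extracts
#' maximal simple paths. Symbols of degree greater than two are conflicts:
#' each of their incident edges starts its own path. Output is deterministic
#' (paths oriented and sorted lexicographically); cycles are broken at their
#' lexicographically smallest symbol and flagged.
#'
#' @param adj Either the two-column matrix stored per node by
#'   [ancestral_adjacencies()], or an `adjacency_set` plus `node`.
#' @param node Node label when `adj` is an `adjacency_set`.
#' @return List with `paths` (list of character vectors), `conflicts`
#'   (symbols with degree > 2) and `cycles` (logical per path).
#' @export
assemble_order <- function(adj, node = NULL) {
  if (inherits(adj, "adjacency_set")) {
    stopifnot(!is.null(node))
    if (!node %in% names(adj$node_adjacencies)) stop("unknown node: ", node)
    adj <- adj$node_adjacencies[[node]]
  }
  if (!nrow(adj)) return(list(paths = list(), conflicts = character(0),
                              cycles = logical(0)))
  edges <- unique(t(apply(adj, 1, function(r) sort(r))))
  deg <- table(c(edges[, 1], edges[, 2]))
  conflicts <- sort(names(deg[deg > 2]))
  # split conflict vertices: every incident edge gets its own copy
  nbr <- list()
  add <- function(a, b) nbr[[a]] <<- c(nbr[[a]], b)
  copy_i <- 0L
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a %in% conflicts) { copy_i <- copy_i + 1L; a <- paste0(a, "\r", copy_i) }
    if (b %in% conflicts) { copy_i <- copy_i + 1L; b <- paste0(b, "\r", copy_i) }
    add(a, b); add(b, a)
  }
  strip <- function(x) sub("\r.*$", "", x)
  verts <- names(nbr)
  visited <- stats::setNames(rep(FALSE, length(verts)), verts)
  paths <- list(); cycles <- logical(0)
  trace <- function(start) {
    path <- start; visited[start] <<- TRUE
    prev <- NA_character_; cur <- start
    repeat {
      nxt <- setdiff(nbr[[cur]], c(prev, NA))
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      nxt <- sort(nxt)[1]
      path <- c(path, nxt); visited[nxt] <<- TRUE
      prev <- cur; cur <- nxt
    }
    path
  }
  ends <- sort(verts[vapply(verts, function(v) length(nbr[[v]]) == 1L, TRUE)])
  for (v in ends) {
    if (visited[v]) next
    p <- strip(trace(v))
    paths[[length(paths) + 1L]] <- p
    cycles <- c(cycles, FALSE)
  }
  for (v in sort(verts)) {            # remaining components are cycles
    if (visited[v]) next
    p <- strip(trace(v))
    paths[[length(paths) + 1L]] <- p
    cycles <- c(cycles, TRUE)
  }
  # canonical orientation and order
  paths <- lapply(paths, function(p)
    if (paste(rev(p), collapse = "\r") < paste(p, collapse = "\r")) rev(p) else p)
  o <- order(vapply(paths, function(p) paste(p, collapse = "\r"), ""))
  list(paths = paths[o], conflicts = conflicts, cycles = cycles[o])
}
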