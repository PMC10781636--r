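# Placing gene origins, duplications and losses on a species tree.
#
# Two reconstructions are provided. `dollo_reconstruct()` uses the presence
# matrix alone: each clade is gained once at the MRCA of its carriers and
# lost on the minimal set of branches below. `reconcile()` additionally uses
# the gene-family (clade) tree: every clade-tree node is mapped to the
# species-tree LCA of its descendant carriers; nodes whose children map to
# comparable species nodes are duplications, and a clade's origin is pushed
# rootward to the species branch of its nearest ancestral duplication.
# Pseudogene cells count as carriers (evidence of ancestral presence) and
# are additionally reported as pseudogenization events on terminal branches.

.event_row <- function(branch, kind, clade, parent_clade = NA_character_) {
  data.frame(branch = branch, kind = kind, clade = clade,
             parent_clade = parent_clade, row.names = NULL)
}

.empty_events <- function() {
  data.frame(branch = character(0), kind = character(0), clade = character(0),
             parent_clade = character(0))
}

# Place one clade by Dollo parsimony from `origin` (node number); record
# presence into `rep_env` (an environment holding a list keyed by node
# label) and return event rows.
.place_clade_dollo <- function(idx, pm, clade, origin, rep_env) {
  carriers <- .carriers(pm, clade)
  present <- .dollo_present(idx, origin, carriers)
  losses <- .dollo_losses(idx, origin, present)
  for (v in present) {
    lbl <- idx$labels[v]
    status <- if (v <= idx$ntip && pm$states[lbl, clade] == "pseudogene")
      "pseudogene" else "intact"
    rep_env$rep[[lbl]] <- rbind(rep_env$rep[[lbl]],
                                data.frame(clade = clade, status = status))
  }
  ev <- .empty_events()
  for (v in losses) ev <- rbind(ev, .event_row(idx$labels[v], "loss", clade))
  pseudo <- carriers[pm$states[carriers, clade] == "pseudogene"]
  for (s in pseudo) ev <- rbind(ev, .event_row(s, "pseudogenization", clade))
  ev
}

.new_rep_env <- function(idx) {
  e <- new.env(parent = emptyenv())
  e$rep <- stats::setNames(vector("list", idx$ntip + idx$nnode), idx$labels)
  e
}

.finish_repertoire <- function(idx, rep_env) {
  rep <- lapply(rep_env$rep, function(d) {
    if (is.null(d)) data.frame(clade = character(0), status = character(0))
    else d[order(d$clade), , drop = FALSE]
  })
  structure(list(repertoire = rep, tree = idx), class = "ancestral_repertoire")
}

#' Matrix-only Dollo reconstruction of gene gains and losses
#'
#' Each clade originates once, at the MRCA of its carrier species
#' (pseudogenes count as carriers), and is lost on the minimal set of
#' branches below the origin such that exactly the carriers retain it. The
#' loss count is minimal among all single-origin histories; equal-cost
#' placements are resolved rootward, which the spanning-subtree construction
#' yields automatically.
#'
#' @param species_tree `phylo` or [tree_index()].
#' @param pm A [presence_matrix()].
#' @return A list of class `event_map` with elements `events` (data.frame
#'   `branch`, `kind`, `clade`, `parent_clade`; branches are named by their
#'   child node), `repertoire` (an `ancestral_repertoire`), `origins` (named
#'   character vector clade -> origin node label) and `tree`.
#' @export
dollo_reconstruct <- function(species_tree, pm) {
  idx <- tree_index(species_tree)
  stopifnot(inherits(pm, "presence_matrix"))
  ev <- .empty_events()
  rep_env <- .new_rep_env(idx)
  origins <- character(0)
  for (clade in pm$clades) {
    carriers <- .carriers(pm, clade)
    if (!length(carriers)) stop("clade with zero carriers: ", clade)
    origin <- .mrca_nodes(idx, .node_id(idx, carriers))
    origins[clade] <- idx$labels[origin]
    ev <- rbind(ev, .event_row(idx$labels[origin], "origin", clade),
                .place_clade_dollo(idx, pm, clade, origin, rep_env))
  }
  structure(list(events = ev, repertoire = .finish_repertoire(idx, rep_env),
                 origins = origins, tree = idx),
            class = "event_map")
}

# Label for a clade-tree node: the clade itself for leaves, otherwise
# "anc(a+b+...)" over the descendant clade labels.
.lineage_name <- function(cidx, v) {
  if (v <= cidx$ntip) return(cidx$labels[v])
  paste0("anc(", paste(sort(cidx$leafset[[v]]), collapse = "+"), ")")
}

#' Reconcile a clade tree with the species tree
#'
#' LCA reconciliation at the level of ortholog clades. Every clade-tree node
#' is mapped to the species-tree MRCA of its descendant carriers (from the
#' presence matrix). An internal node is a duplication when the mappings of
#' at least two children are comparable (one an ancestor of the other, which
#' includes equality); duplications are placed on that species branch, and
#' sister clades born of one duplication originate on the same branch. Each
#' clade's origin is therefore the mapping of its nearest ancestral
#' duplication — at or rootward of the matrix-only Dollo origin. Losses are
#' then placed per clade exactly as in [dollo_reconstruct()], starting from
#' the reconciled origin.
#'
#' @param clade_tree Rooted `phylo` whose tips are clade labels (matching the
#'   matrix columns), or a `labelled_gene_tree` from [label_duplications()]
#'   together with `...` arguments for [extract_clades()], in which case the
#'   gene tree is first collapsed to its clade tree.
#' @param species_tree `phylo` or [tree_index()].
#' @param pm A [presence_matrix()].
#' @param ... Passed to [extract_clades()] when `clade_tree` is a labelled
#'   gene tree.
#' @return An `event_map` (see [dollo_reconstruct()]); `origins` gives each
#'   clade's reconciled origin branch, and `events` additionally contains
#'   `duplication` rows whose `clade`/`parent_clade` columns use ancestral
#'   lineage labels `anc(...)` for internal lineages.
#' @export
reconcile <- function(clade_tree, species_tree, pm, ...) {
  if (inherits(clade_tree, "labelled_gene_tree"))
    clade_tree <- collapse_to_clade_tree(clade_tree, ...)
  sidx <- tree_index(species_tree)
  cidx <- tree_index(clade_tree)
  stopifnot(inherits(pm, "presence_matrix"))
  clades <- cidx$labels[seq_len(cidx$ntip)]
  missing <- setdiff(clades, pm$clades)
  if (length(missing))
    stop("clade in tree but absent from matrix: ", paste(missing, collapse = ", "))

  n <- cidx$ntip + cidx$nnode
  M <- integer(n)                      # species node each clade node maps to
  for (v in cidx$postorder) {
    if (v <= cidx$ntip) {
      carriers <- .carriers(pm, cidx$labels[v])
      if (!length(carriers)) stop("clade with zero carriers: ", cidx$labels[v])
      M[v] <- .mrca_nodes(sidx, .node_id(sidx, carriers))
    } else {
      M[v] <- .mrca_nodes(sidx, M[cidx$children[[v]]])
    }
  }
  is_dup <- logical(n)
  for (v in cidx$postorder) {
    if (v <= cidx$ntip) next
    kids <- cidx$children[[v]]
    for (i in seq_len(length(kids) - 1L)) {
      for (j in (i + 1L):length(kids)) {
        a <- M[kids[i]]; b <- M[kids[j]]
        if (.is_ancestor(sidx, a, b) || .is_ancestor(sidx, b, a)) {
          is_dup[v] <- TRUE
        }
      }
    }
  }

  ev <- .empty_events()
  rep_env <- .new_rep_env(sidx)
  origins <- character(0)

  # step from species node `top` one branch toward species node `target`
  step_down <- function(top, target) {
    if (target == top) return(top)     # unary pass-through
    v <- target
    while (sidx$parent[v] != top) v <- sidx$parent[v]
    v
  }
  add_segment <- function(lbls, name) {          # mark internal lineage
    for (l in lbls)
      rep_env$rep[[l]] <- rbind(rep_env$rep[[l]],
                                data.frame(clade = name, status = "intact"))
  }
  path_labels <- function(top, bottom) {         # top..bottom inclusive
    v <- bottom; out <- character(0)
    repeat {
      out <- c(sidx$labels[v], out)
      if (v == top) break
      v <- sidx$parent[v]
    }
    out
  }

  place <- function(v, s_top) {
    name <- .lineage_name(cidx, v)
    if (v <= cidx$ntip) {
      origins[cidx$labels[v]] <<- sidx$labels[s_top]
      ev <<- rbind(ev, .place_clade_dollo(sidx, pm, cidx$labels[v], s_top, rep_env))
      return(invisible())
    }
    if (is_dup[v]) {
      # lineage exists from s_top down to (but not through) the duplication
      pl <- path_labels(s_top, M[v])
      add_segment(pl[-length(pl)], name)
      for (ch in cidx$children[[v]]) {
        ev <<- rbind(ev, .event_row(sidx$labels[M[v]], "duplication",
                                    .lineage_name(cidx, ch), name))
        place(ch, M[v])
      }
    } else {
      # speciation: lineage exists down to and including its mapping, then
      # continues independently in each species-child subtree
      add_segment(path_labels(s_top, M[v]), name)
      covered <- integer(0)
      for (ch in cidx$children[[v]]) {
        s_ch <- step_down(M[v], M[ch])
        covered <- c(covered, s_ch)
        place(ch, s_ch)
      }
      if (!any(covered == M[v]))       # skip bookkeeping for unary nodes
        for (s_ch in setdiff(sidx$children[[M[v]]], covered))
          ev <<- rbind(ev, .event_row(sidx$labels[s_ch], "loss", name))
    }
  }

  root_c <- cidx$root
  ev <- rbind(ev, .event_row(sidx$labels[M[root_c]], "origin",
                             .lineage_name(cidx, root_c)))
  place(root_c, M[root_c])

  structure(list(events = ev, repertoire = .finish_repertoire(sidx, rep_env),
                 origins = origins, tree = sidx,
                 clade_tree = cidx,
                 mapping = stats::setNames(sidx$labels[M],
                                           vapply(seq_len(n), function(v)
                                             .lineage_name(cidx, v), "")),
                 is_duplication = is_dup),
            class = "event_map")
}

#' Collapse a labelled gene tree to its clade tree
#'
#' Extracts ortholog clades with [extract_clades()] and returns the tree over
#' clade labels obtained by replacing each clade's subtree with a single tip
#' (internal structure between clades is kept; unary nodes are suppressed).
#'
#' @inheritParams extract_clades
#' @return A `phylo` whose tips are clade labels.
#' @export
collapse_to_clade_tree <- function(labelled, level = "clade",
                                   taxon_groups = NULL, labels = NULL) {
  ca <- extract_clades(labelled, level = level, taxon_groups = taxon_groups,
                       labels = labels)
  lab <- labelled
  clade_of <- stats::setNames(ca$clade, ca$gene)
  emitted <- character(0)
  build <- function(v) {
    cl <- unique(unname(clade_of[lab$leafset[[v]]]))
    if (length(cl) == 1L) {
      # a clade is placed once, at its topmost pure subtree
      if (cl %in% emitted) return("")
      emitted <<- c(emitted, cl)
      return(cl)
    }
    kids <- vapply(lab$children[[v]], build, "")
    kids <- kids[nzchar(kids)]
    if (length(kids) <= 1L) return(if (length(kids)) kids else "")
    paste0("(", paste(kids, collapse = ","), ")")
  }
  nw <- build(lab$root)
  if (!startsWith(nw, "(")) nw <- paste0("(", nw, ")")
  read_newick(paste0(nw, ";"))
}

#' Size of the repertoire at a species-tree node
#'
#' @param x An `ancestral_repertoire` or an `event_map`.
#' @param node Node label (internal or tip) of the species tree.
#' @param count_pseudogenes Count clades present only as pseudogenes?
#' @return Integer number of gene lineages present at the node.
#' @export
ancestral_repertoire_size <- function(x, node, count_pseudogenes = FALSE) {
  rep <- if (inherits(x, "event_map")) x$repertoire else x
  stopifnot(inherits(rep, "ancestral_repertoire"))
  if (!node %in% names(rep$repertoire)) stop("unknown node: ", node)
  d <- rep$repertoire[[node]]
  if (!count_pseudogenes) d <- d[d$status == "intact", , drop = FALSE]
  length(unique(d$clade))
}

#' Clades present at a species-tree node
#'
#' @inheritParams ancestral_repertoire_size
#' @return Character vector of lineage labels, sorted.
#' @export
repertoire_at <- function(x, node, count_pseudogenes = TRUE) {
  rep <- if (inherits(x, "event_map")) x$repertoire else x
  stopifnot(inherits(rep, "ancestral_repertoire"))
  if (!node %in% names(rep$repertoire)) stop("unknown node: ", node)
  d <- rep$repertoire[[node]]
  if (!count_pseudogenes) d <- d[d$status == "intact", , drop = FALSE]
  sort(unique(d$clade))
}

#' Losses placed on a species-tree branch
#'
#' Branches are identified by the label of their child node.
#'
#' @param em An `event_map`.
#' @param branch Child-node label.
#' @return Sorted character vector of clade labels lost on the branch.
#' @export
losses_on_branch <- function(em, branch) {
  stopifnot(inherits(em, "event_map"))
  if (!branch %in% em$tree$labels) stop("unknown branch: ", branch)
  sort(em$events$clade[em$events$kind == "loss" & em$events$branch == branch])
}

#' Replay an event map down the species tree
#'
#' Starting from an empty repertoire at the root, applies origin, loss and
#' pseudogenization events branch by branch and returns the resulting state
#' of every clade at every tip. Used to verify that a reconstruction
#' reproduces its input matrix exactly.
#'
#' @param em An `event_map` from [dollo_reconstruct()] (leaf-clade labels
#'   only).
#' @return A [presence_matrix()] over the tips of the species tree.
#' @export
replay_events <- function(em) {
  stopifnot(inherits(em, "event_map"))
  idx <- em$tree
  ev <- em$events
  clades <- sort(unique(ev$clade[ev$kind %in% c("origin")]))
  states <- matrix("absent", idx$ntip, length(clades),
                   dimnames = list(idx$labels[seq_len(idx$ntip)], clades))
  state_at <- vector("list", idx$ntip + idx$nnode)
  for (v in idx$preorder) {
    s <- if (idx$parent[v] == 0L) character(0) else state_at[[idx$parent[v]]]
    b <- idx$labels[v]
    s <- union(s, ev$clade[ev$kind == "origin" & ev$branch == b])
    s <- setdiff(s, ev$clade[ev$kind == "loss" & ev$branch == b])
    state_at[[v]] <- s
    if (v <= idx$ntip) {
      states[b, intersect(s, clades)] <- "intact"
      pse <- ev$clade[ev$kind == "pseudogenization" & ev$branch == b]
      states[b, intersect(pse, clades)] <- "pseudogene"
    }
  }
  presence_matrix(states)
}

#' Compare two gene models and report intron gains and losses
#'
#' Exons are aligned by cumulative coding length: a boundary present in one
#' model but absent in the other is an intron gain (in the derived model) or
#' an intron loss. The two models must have the same total coding length
#' (within `tolerance`).
#'
#' @param reference,derived [gene_model()] objects.
#' @param tolerance Allowed difference in total coding length (bases).
#' @return A list with `intron_gains` / `intron_losses` (data.frames with the
#'   reference exon index and the coding offset of each new/removed boundary),
#'   `exon_count_reference`, `exon_count_derived` and `exon_count_delta`.
#' @export
compare_gene_models <- function(reference, derived, tolerance = 0) {
  stopifnot(inherits(reference, "gene_model"), inherits(derived, "gene_model"))
  len <- function(gm) gm$exons[, 2] - gm$exons[, 1]
  lr <- len(reference); ld <- len(derived)
  if (abs(sum(lr) - sum(ld)) > tolerance)
    stop("total coding length differs by ", abs(sum(lr) - sum(ld)),
         " bases (> tolerance)")
  br <- cumsum(lr)[-length(lr)]        # internal boundaries, coding offsets
  bd <- cumsum(ld)[-length(ld)]
  gains <- setdiff(bd, br)
  losses <- setdiff(br, bd)
  exon_of <- function(off) findInterval(off - 1L, c(0L, cumsum(lr))) # 1-based
  list(
    intron_gains = data.frame(reference_exon = vapply(gains, exon_of, 1L),
                              coding_offset = gains),
    intron_losses = data.frame(reference_exon = vapply(losses, exon_of, 1L),
                               coding_offset = losses),
    exon_count_reference = length(lr),
    exon_count_derived = length(ld),
    exon_count_delta = length(ld) - length(lr))
}
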