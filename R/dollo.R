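# Shared Dollo parsimony primitives.
#
# Under Dollo parsimony a binary character (a gene clade, an adjacency) is
# gained exactly once and may only be lost afterwards. Given the gain node
# and the carrier tips, the minimal-loss history places the character on the
# spanning subtree connecting the gain node to every carrier; losses fall on
# the branches leaving that subtree. Pruning at the highest possible branch
# is both minimal and the rootward-most of all equal-cost placements, so the
# result is deterministic even on polytomies.

# Nodes (numbers) on the union of paths from `origin` down to each carrier
# tip. Carriers must be tip labels below `origin`.
.dollo_present <- function(idx, origin, carrier_tips) {
  ids <- .node_id(idx, carrier_tips)
  present <- logical(idx$ntip + idx$nnode)
  for (v in ids) {
    while (v != 0L && !present[v]) {
      present[v] <- TRUE
      if (v == origin) break
      v <- idx$parent[v]
    }
  }
  if (!present[origin])
    stop("origin node is not an ancestor of the carriers")
  which(present)
}

# Branches (child-node numbers) on which the character is lost: child not
# present while its parent is, parent at or below origin.
.dollo_losses <- function(idx, origin, present_nodes) {
  present <- logical(idx$ntip + idx$nnode)
  present[present_nodes] <- TRUE
  losses <- integer(0)
  for (v in present_nodes) {
    for (ch in idx$children[[v]]) if (!present[ch]) losses <- c(losses, ch)
  }
  sort(losses)
}

# Brute-force oracle used by the test-suite: enumerate every single-origin
# history on a (small) tree and return the minimal loss count. A history is a
# connected rooted subtree S with a unique topmost node (the gain) whose tip
# intersection equals the carrier set; its cost is the number of branches
# leaving S. Exported for testability but not part of the stable API.
#' @keywords internal
#' @export
dollo_min_losses_bruteforce <- function(tree, carrier_tips) {
  idx <- tree_index(tree)
  n <- idx$ntip + idx$nnode
  internals <- setdiff(seq_len(n), seq_len(idx$ntip))
  carriers <- .node_id(idx, carrier_tips)
  tip_state <- logical(idx$ntip); tip_state[carriers] <- TRUE
  best <- Inf
  for (mask in 0:(2^length(internals) - 1L)) {
    present <- logical(n)
    present[carriers] <- TRUE
    present[internals[bitwAnd(bitwShiftR(mask, seq_along(internals) - 1L), 1L) == 1L]] <- TRUE
    # single origin: every present node except one has a present parent
    tops <- vapply(which(present), function(v)
      idx$parent[v] == 0L || !present[idx$parent[v]], TRUE)
    if (sum(tops) != 1L) next
    losses <- 0L
    for (v in which(present))
      losses <- losses + sum(!present[idx$children[[v]]])
    best <- min(best, losses)
  }
  best
}
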