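# Seeded generators used to validate every stage of the pipeline.
#
# simulate_family() runs a Gillespie birth-death process for gene copies
# along a dated species tree. Every duplication on an internal species
# branch splits the current clade into two new clades (cutting the gene
# genealogy at duplication nodes is exactly how ortholog clades are defined);
# duplications on terminal branches create within-species copies and do not
# split. When one daughter of a duplication goes extinct the surviving
# daughter is merged back into the parent clade, because that duplication
# leaves no trace in observable data (a "hidden" event).

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Simulate gene birth and death along a dated species tree
#'
#' @param species_tree `phylo` with branch lengths in Ma.
#' @param lambda Duplication rate (events per gene lineage per Ma).
#' @param mu Loss rate (events per gene lineage per Ma).
#' @param psi Probability that a surviving tip copy is a pseudogene.
#' @param root_copies Number of gene lineages at the root (each founds its
#'   own clade).
#' @param seed Mandatory integer seed.
#' @param retry_cap Families extinct in all species are resampled at most
#'   this many times before giving up.
#' @return A list with `gene_tree` (`phylo`, `NULL` if all attempts went
#'   extinct), `species_map`, `pm` (a [presence_matrix()] whose columns are
#'   true clade ids), `truth` (list: `clade_origin` named vector clade ->
#'   species branch label of the founding duplication, `"<root>"` for root
#'   clades; `clade_genes` list of gene ids per clade; `events` data.frame of
#'   duplications/losses with their branch; `n_hidden` count of merged
#'   hidden duplications; `attempts`).
#' @export
simulate_family <- function(species_tree, lambda = 5e-4, mu = 1e-4,
                            psi = 0, root_copies = 1, seed, retry_cap = 20) {
  stopifnot(lambda >= 0, mu >= 0, !missing(seed))
  idx <- tree_index(species_tree)
  if (is.null(idx$phy$edge.length)) stop("species tree must be dated (branch lengths)")
  blen <- numeric(idx$ntip + idx$nnode)
  blen[idx$phy$edge[, 2]] <- idx$phy$edge.length
  .with_seed(seed, {
    for (attempt in seq_len(retry_cap)) {
      res <- .sim_family_once(idx, blen, lambda, mu, psi, root_copies)
      if (!is.null(res$gene_tree)) {
        res$truth$attempts <- attempt
        return(res)
      }
    }
    list(gene_tree = NULL, species_map = NULL, pm = NULL,
         truth = list(attempts = retry_cap, extinct = TRUE))
  })
}

.sim_family_once <- function(idx, blen, lambda, mu, psi, root_copies) {
  st <- new.env(parent = emptyenv())
  st$comp <- 0L; st$gene <- 0L; st$dup <- 0L; st$spec <- 0L
  st$origin <- character(0)      # clade id -> branch label of founding dup
  st$alias <- character(0)       # merged clade -> surviving parent clade
  st$events <- list()
  st$leaves <- list()            # gene id -> list(species, comp, pseudo)
  st$n_hidden <- 0L
  new_comp <- function(branch_label) {
    st$comp <- st$comp + 1L
    id <- sprintf("C%03d", st$comp)
    st$origin[id] <- branch_label
    id
  }
  resolve <- function(c) { while (c %in% names(st$alias)) c <- st$alias[[c]]; c }
  note <- function(branch, kind, comp)
    st$events[[length(st$events) + 1L]] <- data.frame(branch = branch,
                                                     kind = kind, clade = comp)

  # Evolve one lineage of clade `comp` over `t` Ma on the branch ending at
  # species node `v`; returns a nested node list or NULL (extinct).
  evolve <- function(comp, t, v) {
    rate <- lambda + mu
    dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (dt >= t) return(arrive(comp, v))
    if (stats::runif(1L) < lambda / rate) {
      blab <- idx$labels[v]
      terminal <- v <= idx$ntip
      if (terminal) { ca <- comp; cb <- comp }    # within-species copy
      else { ca <- new_comp(blab); cb <- new_comp(blab) }
      left <- evolve(ca, t - dt, v)
      right <- evolve(cb, t - dt, v)
      if (is.null(left) && is.null(right)) return(NULL)
      if (is.null(left) || is.null(right)) {      # hidden duplication
        surv <- if (is.null(left)) right else left
        if (!terminal) {
          st$n_hidden <- st$n_hidden + 1L
          sc <- if (is.null(left)) cb else ca
          st$alias[[sc]] <- comp
          st$origin <- st$origin[setdiff(names(st$origin), setdiff(c(ca, cb), sc))]
        }
        return(surv)
      }
      if (!terminal) note(blab, "duplication", paste(ca, cb, sep = "|"))
      st$dup <- st$dup + 1L
      list(label = sprintf("d%03d", st$dup), branch = blab,
           children = list(left, right))
    } else {
      note(idx$labels[v], "loss", resolve(comp))
      NULL
    }
  }

  # A lineage reaches the end of the branch into species node `v`.
  arrive <- function(comp, v) {
    if (v <= idx$ntip) {
      st$gene <- st$gene + 1L
      gid <- sprintf("g%03d", st$gene)
      st$leaves[[gid]] <- list(species = idx$labels[v], comp = comp,
                               pseudo = psi > 0 && stats::runif(1L) < psi)
      return(list(label = gid, leaf = TRUE))
    }
    kids <- lapply(idx$children[[v]], function(u) evolve(comp, blen[u], u))
    kids <- kids[!vapply(kids, is.null, TRUE)]
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    st$spec <- st$spec + 1L
    list(label = sprintf("s%03d", st$spec), children = kids)
  }

  roots <- lapply(seq_len(root_copies), function(i) {
    comp <- new_comp("<root>")
    evolve(comp, blen[idx$root], idx$root)   # root branch length may be 0
  })
  roots <- roots[!vapply(roots, is.null, TRUE)]
  if (!length(roots)) return(list(gene_tree = NULL))
  top <- if (length(roots) == 1L) roots[[1L]] else {
    st$dup <- st$dup + 1L
    list(label = sprintf("d%03d", st$dup), branch = idx$labels[idx$root],
         children = roots)
  }
  if (!is.null(top$leaf) || is.null(top$children)) return(list(gene_tree = NULL))

  to_newick <- function(nd) {
    if (!is.null(nd$leaf)) return(nd$label)
    paste0("(", paste(vapply(nd$children, to_newick, ""), collapse = ","),
           ")", nd$label)
  }
  gt <- read_newick(paste0(to_newick(top), ";"))
  genes <- names(st$leaves)
  species_map <- vapply(st$leaves, function(l) l$species, "")
  comp_map <- vapply(st$leaves, function(l) resolve(l$comp), "")
  pseudo <- vapply(st$leaves, function(l) l$pseudo, TRUE)
  comps <- sort(unique(comp_map))
  states <- matrix("absent", idx$ntip, length(comps),
                   dimnames = list(idx$labels[seq_len(idx$ntip)], comps))
  copies <- matrix(0L, idx$ntip, length(comps), dimnames = dimnames(states))
  for (i in seq_along(genes)) {
    sp <- species_map[i]; cp <- comp_map[i]
    copies[sp, cp] <- copies[sp, cp] + 1L
    states[sp, cp] <- if (pseudo[i] && states[sp, cp] != "intact")
      "pseudogene" else "intact"
  }
  ev <- if (length(st$events)) do.call(rbind, st$events)
        else data.frame(branch = character(0), kind = character(0),
                        clade = character(0))
  list(gene_tree = gt, species_map = species_map,
       pm = presence_matrix(states, copies),
       truth = list(clade_origin = st$origin[comps],
                    clade_genes = split(genes, comp_map),
                    pseudogene = pseudo, events = ev,
                    n_hidden = st$n_hidden, extinct = FALSE))
}

#' Simulate upstream windows with a planted motif word
#'
#' Generates one i.i.d.-background window per species at the requested GC
#' content and plants `word` (on a random strand when `strands = "both"`) at
#' a uniform offset in each carrier species.
#'
#' @param species Character vector of species ids.
#' @param word Motif word to plant (DNA alphabet).
#' @param carrier_species Species that receive the planted word.
#' @param L Window length (bases upstream of the start codon).
#' @param gc Background GC content.
#' @param strands `"both"` or `"plus"`.
#' @param seed Mandatory integer seed.
#' @return List with `windows` (named [Biostrings::DNAStringSet]) and `truth`
#'   (data.frame `species`, `offset` (start, relative to the start codon,
#'   negative), `strand`).
#' @export
simulate_upstream <- function(species, word = "ATGCAAAT", carrier_species,
                              L = 300, gc = 0.42, strands = c("both", "plus"),
                              seed) {
  strands <- match.arg(strands)
  w <- nchar(word)
  if (L < w) stop("window length shorter than the word")
  stopifnot(!missing(seed), all(carrier_species %in% species))
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(species, function(s)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
    truth <- data.frame(species = character(0), offset = integer(0),
                        strand = character(0))
    for (s in carrier_species) {
      pos <- sample.int(L - w + 1L, 1L)              # 1-based within window
      strand <- if (strands == "both" && stats::runif(1L) < 0.5) "-" else "+"
      planted <- if (strand == "+") word else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(word)))
      substr(seqs[s], pos, pos + w - 1L) <- planted
      truth <- rbind(truth, data.frame(species = s, offset = pos - L - 1L,
                                       strand = strand))
    }
    list(windows = Biostrings::DNAStringSet(seqs), truth = truth, word = word,
         L = L)
  })
}

#' Simulate an assay plate of AUC responses
#'
#' Emulates the replicate structure of the luminescence assay: independent
#' experiments with duplicate wells per (receptor pair, ligand) row, plus
#' matched buffer-control wells on every experiment. Responder rows get a
#' mean shift of `delta` RLU over control.
#'
#' @param pairs Character vector of receptor-pair ids.
#' @param ligands Character vector of ligand ids.
#' @param effect_rows Data frame with columns `pair`, `ligand` (rows that
#'   truly respond), or `NULL` for a fully null plate.
#' @param delta Mean AUC shift of responder rows (RLU).
#' @param sigma Well-level noise s.d. (RLU).
#' @param n_experiments Independent experiments per row.
#' @param n_wells Duplicate wells per experiment.
#' @param seed Mandatory integer seed.
#' @return List with `table` (data.frame `pair`, `ligand`, `experiment`,
#'   `well`, `auc`, `is_control`) and `truth` (the effect rows).
#' @export
simulate_assay <- function(pairs, ligands, effect_rows = NULL, delta = 30000,
                           sigma = 5000, n_experiments = 6, n_wells = 2,
                           seed) {
  stopifnot(!missing(seed))
  .with_seed(seed, {
    rows <- expand.grid(pair = pairs, ligand = c(ligands, "__buffer__"),
                        experiment = seq_len(n_experiments),
                        well = seq_len(n_wells),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$pair, rows$ligand, rows$experiment, rows$well), ]
    is_eff <- rep(FALSE, nrow(rows))
    if (!is.null(effect_rows) && nrow(effect_rows))
      is_eff <- paste(rows$pair, rows$ligand) %in%
        paste(effect_rows$pair, effect_rows$ligand)
    rows$auc <- stats::rnorm(nrow(rows), mean = ifelse(is_eff, delta, 0),
                             sd = sigma)
    rows$is_control <- rows$ligand == "__buffer__"
    rows$ligand[rows$is_control] <- "buffer"
    rownames(rows) <- NULL
    list(table = rows,
         truth = if (is.null(effect_rows))
           data.frame(pair = character(0), ligand = character(0))
         else effect_rows)
  })
}
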