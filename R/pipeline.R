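# End-to-end orchestration: clades -> reconstruction -> synteny -> motif ->
# assay, with a deterministic JSON/Markdown report.

#' Default pipeline configuration
#'
#' @param seed Seed for any stochastic stage.
#' @param rlu_threshold,q_max Responder rule thresholds.
#' @param motif_word IUPAC word scanned upstream.
#' @param min_species Species support required to call the motif conserved.
#' @param max_intervening Non-family genes allowed inside a cluster.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1, rlu_threshold = 10000, q_max = 0.01,
                       motif_word = "ATGCAAAT", min_species = 4,
                       max_intervening = 0) {
  cfg <- list(seed = seed, rlu_threshold = rlu_threshold, q_max = q_max,
              motif_word = motif_word, min_species = min_species,
              max_intervening = max_intervening)
  if (any(c(rlu_threshold, q_max, min_species) <= 0))
    stop("thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected.
#'
#' @param file YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full reconstruction pipeline
#'
#' Executes, on a fixture-shaped input bundle (see [tas1r_fixture()]): clade
#' extraction from the gene tree, reconciliation of the clade tree with the
#' species tree, cluster/adjacency analysis of the gene orders, the upstream
#' motif scan with a conservation call, and responder calling on the assay
#' table. Returns a deterministic report.
#'
#' @param config A `run_config`.
#' @param data Input bundle; defaults to [tas1r_fixture()]. Must contain
#'   `species_tree` and `pm`; the other components are optional and their
#'   stages are skipped when absent.
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config = run_config(), data = tas1r_fixture()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = unclass(config))

  if (!is.null(data$gene_tree)) {
    lab <- label_duplications(data$gene_tree, data$species_map)
    ca <- extract_clades(lab, level = "clade",
                         taxon_groups = data$taxon_groups,
                         labels = data$clade_labels)
    report$n_clades <- length(unique(ca$clade))
    report$clade_assignment <- ca
  }

  if (ncol(data$pm$states) > 0) {
    em <- if (!is.null(data$clade_tree))
      reconcile(data$clade_tree, data$species_tree, data$pm)
    else dollo_reconstruct(data$species_tree, data$pm)
    idx <- tree_index(data$species_tree)
    sizes <- vapply(idx$labels, function(l)
      ancestral_repertoire_size(em, l), 0L)
    report$events <- em$events
    report$origins <- em$origins
    report$repertoire_sizes <- sizes
    report$n_events <- nrow(em$events)
  } else {
    report$events <- .empty_events()
    report$n_events <- 0L
    report$repertoire_sizes <- integer(0)
  }

  if (!is.null(data$gene_orders)) {
    report$clusters <- lapply(data$gene_orders, detect_clusters,
                              max_intervening = config$max_intervening)
    names(report$clusters) <- vapply(data$gene_orders, function(o)
      paste(o$species[1], o$scaffold[1], sep = ":"), "")
    anc <- ancestral_adjacencies(data$species_tree, data$gene_orders,
                                 collapse_family = TRUE)
    report$ancestral_orders <- lapply(
      anc$node_adjacencies[vapply(anc$node_adjacencies, nrow, 0L) > 0],
      function(m) assemble_order(m)$paths)
  }

  if (!is.null(data$upstream)) {
    hits <- scan_word(data$upstream$windows, config$motif_word)
    cons <- conservation_call(hits, data$species_tree,
                              min_species = config$min_species)
    report$motif_hits <- hits
    report$motif_conserved <- cons$conserved
    report$motif_support <- cons$supporting_species
  }

  if (!is.null(data$assay)) {
    calls <- call_responders(data$assay$table,
                             threshold = config$rlu_threshold,
                             q_max = config$q_max)
    report$responder_calls <- calls
    pos <- calls[calls$call == "positive", ]
    if (!is.null(data$assay$amino_acids)) {
      aa <- data$assay$amino_acids
      resp_aa <- sort(unique(pos$ligand[pos$ligand %in% aa$ligand]))
      report$responder_amino_acids <- resp_aa
      report$enrichment_p <- fisher_enrichment(
        nrow(aa), sum(aa$essential), length(resp_aa),
        sum(resp_aa %in% aa$ligand[aa$essential]))
    }
  }

  class(report) <- "pipeline_report"
  report
}

#' Write a pipeline report to JSON and Markdown
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(dir, "report.json")
  mpath <- file.path(dir, "report.md")
  jsonlite::write_json(unclass(report), jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  lines <- c("# Gene-family birth-and-death report", "")
  if (!is.null(report$n_clades))
    lines <- c(lines, sprintf("- ortholog clades: %d", report$n_clades))
  lines <- c(lines, sprintf("- events placed on the species tree: %d",
                            report$n_events))
  if (length(report$repertoire_sizes)) {
    lines <- c(lines, "", "## Ancestral repertoire sizes", "")
    lines <- c(lines, sprintf("- %s: %d", names(report$repertoire_sizes),
                              report$repertoire_sizes))
  }
  if (nrow(report$events)) {
    lines <- c(lines, "", "## Events (branch / kind / clade)", "")
    lines <- c(lines, sprintf("- %s / %s / %s", report$events$branch,
                              report$events$kind, report$events$clade))
  }
  if (!is.null(report$motif_conserved))
    lines <- c(lines, "", sprintf("Motif conserved: %s (support: %s)",
                                  report$motif_conserved,
                                  paste(report$motif_support, collapse = ", ")))
  if (!is.null(report$responder_calls)) {
    pos <- report$responder_calls[report$responder_calls$call == "positive", ]
    lines <- c(lines, "", "## Positive responses", "",
               sprintf("- %s : %s (mean AUC %.0f RLU, q = %.2g)", pos$pair,
                       pos$ligand, pos$mean_auc, pos$q))
    if (!is.null(report$enrichment_p))
      lines <- c(lines, "", sprintf(
        "Essential amino-acid enrichment p = %.3g (one-sided Fisher)",
        report$enrichment_p))
  }
  writeLines(lines, mpath)
  invisible(c(json = jpath, markdown = mpath))
}
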