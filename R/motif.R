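# Upstream-window extraction, IUPAC word scanning, conservation calls and
# position weight matrices.
#
# Offsets follow the convention of counting nucleotide positions back from
# the A of the start codon: the base immediately 5' of ATG is position -1,
# so a window of length L covers -L..-1 and a hit starting at offset `o`
# with width w satisfies o + w <= 0.

#' Extract the upstream window of a gene
#'
#' Returns the sequence immediately 5' of the start codon on the coding
#' strand (reverse-complemented for minus-strand genes), truncated at the
#' scaffold edge and never padded.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector)
#'   of scaffolds.
#' @param model A [gene_model()]; the start codon is the first base of the
#'   first exon in transcription order.
#' @param L Maximum window length in bases.
#' @return A list of class `upstream_window`: `species`, `gene`, `seq`
#'   (character, uppercase), `length`, and `from`/`to` offsets (negative,
#'   relative to the start codon).
#' @export
extract_upstream <- function(genome, model, L = 300) {
  stopifnot(inherits(model, "gene_model"))
  if (!methods::is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  if (!model$scaffold %in% names(genome))
    stop("scaffold not in genome: ", model$scaffold)
  chr <- genome[[model$scaffold]]
  n <- length(chr)
  if (model$strand == "+") {
    start0 <- model$exons[1, 1]               # 0-based start codon position
    if (start0 < 0 || start0 > n) stop("start codon outside scaffold")
    lo <- max(0L, start0 - L)
    s <- if (start0 == 0L) "" else as.character(chr[(lo + 1):start0])
  } else {
    end0 <- model$exons[1, 2]                 # 0-based, exclusive
    if (end0 < 0 || end0 > n) stop("start codon outside scaffold")
    hi <- min(n, end0 + L)
    s <- if (end0 == n) "" else as.character(
      Biostrings::reverseComplement(chr[(end0 + 1):hi]))
  }
  s <- toupper(s)
  structure(list(species = model$species, gene = model$gene_id, seq = s,
                 length = nchar(s), from = -nchar(s), to = -1L),
            class = "upstream_window")
}

.window_seq <- function(w) {
  if (inherits(w, "upstream_window")) w$seq else as.character(w)
}

#' Scan upstream windows for an IUPAC word
#'
#' Finds all exact (IUPAC-compatible) occurrences of `word` in each window,
#' on one or both strands, and reports offsets of the match start relative
#' to the start codon (negative; the last window base is -1).
#'
#' @param windows Named list/vector of windows (`upstream_window` objects,
#'   character sequences or a [Biostrings::DNAStringSet]), named by species.
#' @param word IUPAC word.
#' @param strands `"both"`, `"plus"` or `"minus"`.
#' @return Data frame with columns `species`, `offset`, `strand`, `word`,
#'   ordered by species then offset.
#' @export
scan_word <- function(windows, word = "ATGCAAAT", strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  if (!grepl("^[ACGTUMRWSYKVHDBN]+$", word, ignore.case = TRUE))
    stop("invalid IUPAC character in word: ", word)
  word <- toupper(word)
  if (methods::is(windows, "DNAStringSet")) windows <- as.character(windows)
  if (is.null(names(windows))) stop("windows must be named by species")
  w <- nchar(word)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(word)))
  out <- list()
  for (sp in names(windows)) {
    s <- .window_seq(windows[[sp]])
    L <- nchar(s)
    if (L < w) next
    subj <- Biostrings::DNAString(s)
    hit1 <- if (strands %in% c("both", "plus"))
      Biostrings::start(Biostrings::matchPattern(word, subj, fixed = FALSE))
    else integer(0)
    hit2 <- if (strands %in% c("both", "minus"))
      Biostrings::start(Biostrings::matchPattern(rc, subj, fixed = FALSE))
    else integer(0)
    d <- rbind(
      if (length(hit1)) data.frame(species = sp, offset = hit1 - L - 1L,
                                   strand = "+"),
      if (length(hit2)) data.frame(species = sp, offset = hit2 - L - 1L,
                                   strand = "-"))
    if (!is.null(d) && nrow(d)) out[[sp]] <- d[order(d$offset, d$strand), ]
  }
  if (!length(out))
    return(data.frame(species = character(0), offset = integer(0),
                      strand = character(0), word = character(0)))
  res <- do.call(rbind, out)
  res$word <- word
  rownames(res) <- NULL
  res[order(res$species, res$offset, res$strand), ]
}

#' Call cross-species conservation of a motif
#'
#' A motif is conserved when at least `min_species` species have a hit whose
#' start offset falls inside `band`.
#'
#' @param hits Data frame from [scan_word()].
#' @param species_tree Optional tree; when given, the MRCA of the supporting
#'   species is reported as the spanning clade.
#' @param min_species Minimum number of supporting species.
#' @param band Numeric length-2 offset interval (inclusive) in which hits
#'   count, e.g. `c(-300, -1)`.
#' @return List with `conserved` (logical), `supporting_species`, `n_support`
#'   and `spanning_clade` (node label or `NA`).
#' @export
conservation_call <- function(hits, species_tree = NULL, min_species = 4,
                              band = c(-300, -1)) {
  in_band <- hits$offset >= band[1] & hits$offset <= band[2]
  supp <- sort(unique(hits$species[in_band]))
  clade <- NA_character_
  if (!is.null(species_tree) && length(supp))
    clade <- mrca(species_tree, supp)
  list(conserved = length(supp) >= min_species,
       supporting_species = supp, n_support = length(supp),
       spanning_clade = clade)
}

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount) / (N + 4 * pseudocount)`.
#'
#' @param sites Character vector of equal-length DNA sites.
#' @param pseudocount Added to each base count per column.
#' @return A list of class `pwm`: `prob` (4 x width matrix, rows A/C/G/T),
#'   `pseudocount`, `n_sites`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5) {
  stopifnot(length(sites) >= 1)
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("ragged sites: lengths ", paste(unique(nchar(sites)), collapse = ", "))
  m <- do.call(rbind, strsplit(sites, ""))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(w), function(j)
    vapply(bases, function(b) sum(m[, j] == b), 0), numeric(4))
  prob <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  dimnames(prob) <- list(bases, NULL)
  structure(list(prob = prob, pseudocount = pseudocount,
                 n_sites = length(sites)), class = "pwm")
}

#' Reverse complement of a PWM
#' @param pwm A `pwm`.
#' @return The reverse-complemented `pwm`.
#' @export
reverse_complement_pwm <- function(pwm) {
  p <- pwm$prob[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$prob))), drop = FALSE]
  rownames(p) <- c("A", "C", "G", "T")
  pwm$prob <- p
  pwm
}

# Pearson correlation of two probability columns; degenerate (zero-variance)
# columns compare as 1 when numerically identical, 0 otherwise.
.col_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    return(if (max(abs(a - b)) < 1e-12) 1 else 0)
  stats::cor(a, b)
}

#' Compare two position weight matrices
#'
#' Similarity is the mean column-wise Pearson correlation over the best
#' ungapped alignment offset, searched on both strands (the second matrix is
#' also compared reverse-complemented), requiring at least `min_overlap`
#' aligned columns. The score is symmetric and invariant to
#' reverse-complementing either input.
#'
#' @param pwm_a,pwm_b `pwm` objects (each at least `min_overlap` columns).
#' @param min_overlap Minimum number of aligned columns.
#' @return List with `score` (in `[-1, 1]`), `offset` (of `pwm_b` relative to
#'   `pwm_a` at the optimum) and `strand` (`"+"` or `"-"`).
#' @export
compare_pwm <- function(pwm_a, pwm_b, min_overlap = 6) {
  wa <- ncol(pwm_a$prob); wb <- ncol(pwm_b$prob)
  if (wa < min_overlap || wb < min_overlap)
    stop("PWM shorter than the minimum overlap (", min_overlap, " columns)")
  score_at <- function(b, off) {
    lo <- max(1L, 1L + off); hi <- min(wa, wb + off)
    if (hi - lo + 1L < min_overlap) return(NA_real_)
    js <- lo:hi                                 # columns of a in the overlap
    mean(vapply(js, function(j) .col_cor(pwm_a$prob[, j], b[, j - off]),
                0))
  }
  best <- list(score = -Inf, offset = 0L, strand = "+")
  for (strand in c("+", "-")) {
    b <- if (strand == "+") pwm_b$prob else reverse_complement_pwm(pwm_b)$prob
    for (off in (-(wb - min_overlap)):(wa - min_overlap)) {
      s <- score_at(b, off)
      if (!is.na(s) && s > best$score) best <- list(score = s, offset = off,
                                                    strand = strand)
    }
  }
  best
}

#' Write / read PWMs in JASPAR-style 4-row text
#'
#' @param pwm A `pwm`.
#' @param file Path; for `read_pwm` a path or literal text with a newline.
#' @return `write_pwm` returns the text (invisibly when writing to a file);
#'   `read_pwm` returns a `pwm` (probabilities are renormalised per column).
#' @export
write_pwm <- function(pwm, file = NULL) {
  lines <- vapply(rownames(pwm$prob), function(b)
    paste0(b, " [ ", paste(formatC(pwm$prob[b, ], format = "g"),
                           collapse = " "), " ]"), "")
  if (is.null(file)) return(paste(lines, collapse = "\n"))
  writeLines(lines, file)
  invisible(paste(lines, collapse = "\n"))
}

#' @rdname write_pwm
#' @export
read_pwm <- function(file) {
  txt <- if (grepl("\n", file)) file else paste(readLines(file), collapse = "\n")
  lines <- strsplit(txt, "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  stopifnot(length(lines) == 4)
  vals <- lapply(lines, function(l) {
    body <- sub("^[ACGT]\\s*\\[", "", trimws(l))
    as.numeric(strsplit(trimws(sub("\\]\\s*$", "", body)), "\\s+")[[1]])
  })
  bases <- toupper(substr(trimws(lines), 1, 1))
  m <- do.call(rbind, vals)
  rownames(m) <- bases
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  m <- sweep(m, 2, colSums(m), "/")
  structure(list(prob = m, pseudocount = NA, n_sites = NA), class = "pwm")
}
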