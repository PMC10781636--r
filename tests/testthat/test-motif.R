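test_that("upstream extraction does coordinate arithmetic on both strands", {
  chr <- paste(rep("ACGT", 300), collapse = "")           # 1200 bases
  genome <- c(scaf = chr)
  plus <- gene_model("gP", "sp", "scaf", "+", cbind(1000, 1100))
  w <- extract_upstream(genome, plus, L = 300)
  expect_equal(w$length, 300)
  expect_identical(w$seq, toupper(substr(chr, 701, 1000)))
  # truncation at the scaffold edge, never padded
  near <- gene_model("gN", "sp", "scaf", "+", cbind(50, 150))
  expect_equal(extract_upstream(genome, near, L = 300)$length, 50)
  # minus strand: window is 3' of the last genomic base, reverse-complemented
  minus <- gene_model("gM", "sp", "scaf", "-", cbind(100, 200))
  wm <- extract_upstream(genome, minus, L = 50)
  expect_identical(wm$seq, revcomp(substr(chr, 201, 250)))
  expect_error(extract_upstream(genome,
    gene_model("gE", "sp", "scaf", "+", cbind(2000, 2100)), L = 10),
    "outside scaffold")
})

test_that("a planted word on the minus strand appears in the coding-strand window", {
  word <- "ATGCAAAT"
  set.seed(21)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  # gene on minus strand at [50,150); upstream is [150,450) on plus strand,
  # so plant the reverse complement there
  chr <- bg
  substr(chr, 201, 208) <- revcomp(word)
  wm <- extract_upstream(c(s = chr), gene_model("g", "sp", "s", "-",
                                                cbind(50, 150)), L = 300)
  hits <- scan_word(list(sp = wm), word, strands = "plus")
  expect_true(nrow(hits) >= 1)
})

test_that("word scanning matches the sliding-window oracle incl. IUPAC codes", {
  set.seed(31)
  for (word in c("ATGCAAAT", "ATGCAAWT", "RTGCNAAT")) {
    for (rep in 1:20) {
      L <- sample(20:120, 1)
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      hits <- scan_word(list(sp = s), word)
      plus <- sort(scan_oracle(s, word))
      minus <- sort(scan_oracle(s, revcomp(word)))
      expect_equal(sort(hits$offset[hits$strand == "+"]), plus - L - 1)
      expect_equal(sort(hits$offset[hits$strand == "-"]), minus - L - 1)
    }
  }
  expect_error(scan_word(list(sp = "ACGT"), "AXG"), "invalid IUPAC")
  expect_equal(nrow(scan_word(list(sp = "CCCCCCCCCCCC"), "ATGCAAAT")), 0)
})

test_that("scanning the reverse complement mirrors offsets and strands", {
  set.seed(33)
  for (rep in 1:20) {
    L <- 60
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    h1 <- scan_word(list(sp = s), "ATGCAAAT")
    h2 <- scan_word(list(sp = revcomp(s)), "ATGCAAAT")
    # a + hit starting at 1-based p maps to a - hit at L-p-6 on the rc
    p1 <- sort(h1$offset[h1$strand == "+"] + L + 1)
    p2 <- sort(L - (h2$offset[h2$strand == "-"] + L + 1) - 8 + 2)
    expect_equal(p1, p2)
  }
})

test_that("conservation calls respect the support threshold and band", {
  fx <- tas1r_fixture()
  hits <- scan_word(fx$upstream$windows, "ATGCAAAT")
  cc <- conservation_call(hits, fx$species_tree, min_species = 4,
                          band = c(-300, -1))
  expect_true(cc$conserved)
  carriers <- c("whale_shark", "bamboo_shark", "cloudy_catshark",
                "elephant_fish", "coelacanth", "bichir", "gecko",
                "anole_lizard", "bearded_dragon")
  expect_setequal(cc$supporting_species, carriers)
  none <- conservation_call(hits[0, ], fx$species_tree, min_species = 1)
  expect_false(none$conserved)
  # planted in k of n species: conserved iff k >= min_species
  for (k in c(2, 5)) {
    sim <- simulate_upstream(paste0("s", 1:8), carrier_species = paste0("s", 1:k),
                             seed = 100 + k)
    h <- scan_word(sim$windows, "ATGCAAAT")
    expect_equal(conservation_call(h, min_species = 4)$conserved, k >= 4)
  }
})

test_that("PWM construction matches forced arithmetic and a counting oracle", {
  p0 <- build_pwm(rep("ATGCAAAT", 5), pseudocount = 0)
  expect_equal(unname(p0$prob[, 1]), c(1, 0, 0, 0))     # column A
  expect_true(all(abs(colSums(p0$prob) - 1) < 1e-9))
  p1 <- build_pwm("ATGCAAAT", pseudocount = 0.5)
  expect_equal(unname(p1$prob["A", 1]), 1.5 / 3)
  expect_equal(unname(p1$prob["C", 1]), 0.5 / 3)
  expect_error(build_pwm(c("ACGT", "ACG")), "ragged")
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:12, 1); w <- sample(4:10, 1)
    sites <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = ""), "")
    pc <- stats::runif(1, 0, 1)
    pwm <- build_pwm(sites, pc)
    chars <- do.call(rbind, strsplit(sites, ""))
    for (j in seq_len(w)) for (b in c("A", "C", "G", "T"))
      expect_equal(unname(pwm$prob[b, j]),
                   (sum(chars[, j] == b) + pc) / (n + 4 * pc))
  }
})

test_that("PWM comparison is symmetric, strand-aware and matches enumeration", {
  set.seed(51)
  sites <- replicate(6, paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                              collapse = ""))
  a <- build_pwm(sites)
  expect_equal(compare_pwm(a, a)$score, 1, tolerance = 1e-12)
  expect_equal(compare_pwm(a, a)$offset, 0)
  rc <- reverse_complement_pwm(a)
  cmp <- compare_pwm(a, rc)
  expect_equal(cmp$score, 1, tolerance = 1e-12)
  expect_identical(cmp$strand, "-")
  # symmetry and rc-invariance on perturbed pairs, vs a plain enumeration
  colcor <- function(x, y) {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
      return(if (max(abs(x - y)) < 1e-12) 1 else 0)
    stats::cor(x, y)
  }
  enum <- function(pa, pb, min_overlap = 6) {
    best <- -Inf
    for (strand in 1:2) {
      m <- if (strand == 1) pb$prob else
        pb$prob[c("T", "G", "C", "A"), rev(seq_len(ncol(pb$prob)))]
      if (strand == 2) rownames(m) <- c("A", "C", "G", "T")
      wa <- ncol(pa$prob); wb <- ncol(m)
      for (off in -wb:wa) {
        cs <- c()
        for (j in seq_len(wa)) {
          jb <- j - off
          if (jb >= 1 && jb <= wb) cs <- c(cs, colcor(pa$prob[, j], m[, jb]))
        }
        if (length(cs) >= min_overlap) best <- max(best, mean(cs))
      }
    }
    best
  }
  for (rep in 1:10) {
    w <- sample(6:10, 1)
    b <- build_pwm(replicate(4, paste(
      sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")))
    expect_equal(compare_pwm(a, b)$score, compare_pwm(b, a)$score,
                 tolerance = 1e-9)
    expect_equal(compare_pwm(a, b)$score,
                 compare_pwm(a, reverse_complement_pwm(b))$score,
                 tolerance = 1e-9)
    expect_equal(compare_pwm(a, b)$score, enum(a, b), tolerance = 1e-9)
  }
  short <- build_pwm("ACGTA")
  expect_error(compare_pwm(a, short), "overlap")
})

test_that("PWM text round-trips in 4-row format", {
  pwm <- build_pwm(c("ATGCAAAT", "ATGCAAAT", "ATGGAAAT"))
  txt <- write_pwm(pwm)
  back <- read_pwm(txt)
  expect_equal(back$prob, pwm$prob, tolerance = 1e-6)
})
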