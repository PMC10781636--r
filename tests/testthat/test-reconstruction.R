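test_that("matrix-only Dollo places origins at carrier MRCAs", {
  fx <- tas1r_fixture()
  em <- dollo_reconstruct(fx$species_tree, fx$pm)
  # matrix-only origin of the axolotl+lizard clade is the tetrapod ancestor
  expect_identical(unname(em$origins["TAS1R7"]), "tetrapoda")
  # a clade present everywhere originates at the root with zero losses
  tr <- read_newick("((a,b)ab,(c,d)cd)r;")
  pm <- presence_matrix(matrix("intact", 4, 1,
                               dimnames = list(letters[1:4], "fam")))
  em2 <- dollo_reconstruct(tr, pm)
  expect_identical(unname(em2$origins["fam"]), "r")
  expect_equal(sum(em2$events$kind == "loss"), 0)
  expect_error(dollo_reconstruct(tr, presence_matrix(
    matrix("absent", 4, 1, dimnames = list(letters[1:4], "fam")))),
    "zero carriers")
})

test_that("Dollo loss counts equal the exhaustive minimum on small trees", {
  set.seed(7)
  for (rep in 1:150) {
    n <- sample(3:6, 1)
    tr <- random_tree(n)
    pm <- random_presence(tr, n_clades = 2)
    em <- dollo_reconstruct(tr, pm)
    for (cl in pm$clades) {
      carriers <- rownames(pm$states)[pm$states[, cl] != "absent"]
      got <- sum(em$events$kind == "loss" & em$events$clade == cl)
      expect_equal(got, dollo_min_losses_bruteforce(tr, carriers))
    }
  }
})

test_that("event replay reproduces the input matrix", {
  fx <- tas1r_fixture()
  em <- dollo_reconstruct(fx$species_tree, fx$pm)
  expect_true(pm_equal(replay_events(em), fx$pm))
  set.seed(11)
  for (rep in 1:50) {
    tr <- random_tree(sample(4:10, 1))
    pm <- random_presence(tr, n_clades = 3)
    expect_true(pm_equal(replay_events(dollo_reconstruct(tr, pm)), pm))
  }
})

test_that("reconciliation pushes origins rootward of the matrix-only Dollo origin", {
  fx <- tas1r_fixture()
  em <- reconcile(fx$clade_tree, fx$species_tree, fx$pm)
  dm <- dollo_reconstruct(fx$species_tree, fx$pm)
  sidx <- tree_index(fx$species_tree)
  for (cl in fx$clades) {
    a <- sidx$node_of[em$origins[cl]]   # reconcile origin
    b <- sidx$node_of[dm$origins[cl]]   # matrix-only origin
    expect_true(genefambd:::.is_ancestor(sidx, a, b), label = cl)
  }
  # sister clades born of one duplication originate on the same branch
  expect_identical(unname(em$origins["TAS1R3A"]), unname(em$origins["TAS1R3B"]))
  # the ray-finned TAS1R2 clade originates on the bony-vertebrate stem and is
  # lost on the lobe-finned stem
  expect_identical(unname(em$origins["TAS1R2B"]), "osteichthyes")
  expect_identical(losses_on_branch(em, "sarcopterygii"), "TAS1R2B")
})

test_that("reconciliation reports ancestral repertoires and branch losses", {
  fx <- tas1r_fixture()
  em <- reconcile(fx$clade_tree, fx$species_tree, fx$pm)
  expect_equal(ancestral_repertoire_size(em, "jawed_vertebrata"), 5)
  expect_equal(ancestral_repertoire_size(em, "osteichthyes"), 9)
  expect_identical(losses_on_branch(em, "tetrapoda"), "TAS1R8")
  expect_identical(losses_on_branch(em, "amniota"), c("TAS1R3B", "TAS1R5"))
  expect_identical(losses_on_branch(em, "human"), c("TAS1R4", "TAS1R7"))
  expect_error(losses_on_branch(em, "atlantis"), "unknown branch")
  expect_error(ancestral_repertoire_size(em, "atlantis"), "unknown node")
  # tip repertoires equal the matrix
  for (sp in rownames(fx$pm$states)) {
    want <- sort(colnames(fx$pm$states)[fx$pm$states[sp, ] != "absent"])
    expect_identical(repertoire_at(em, sp), want, label = sp)
  }
  # pseudogenization is reported on the carrier's terminal branch
  expect_true(any(em$events$kind == "pseudogenization" &
                    em$events$branch == "whale_shark" &
                    em$events$clade == "TAS1R3C"))
  expect_error(reconcile(read_newick("(TAS1R1,NOSUCH);"), fx$species_tree,
                         fx$pm), "absent from matrix")
})

test_that("gene-model comparison recovers intron gains", {
  fx <- tas1r_fixture()
  d <- compare_gene_models(fx$gene_models$reference, fx$gene_models$derived)
  expect_equal(nrow(d$intron_gains), 2)
  expect_equal(sort(d$intron_gains$reference_exon), c(3, 6))
  expect_equal(d$exon_count_derived, 8)
  expect_equal(d$exon_count_delta, 2)
  # identical models: empty diff
  d0 <- compare_gene_models(fx$gene_models$reference, fx$gene_models$reference)
  expect_equal(nrow(d0$intron_gains) + nrow(d0$intron_losses), 0)
  # random models with k simulated intron insertions: exactly k gains
  set.seed(3)
  for (rep in 1:25) {
    lens <- sample(100:900, sample(3:6, 1))
    starts <- cumsum(c(0, utils::head(lens, -1) + 200))
    ref <- gene_model("ref", "sp", "s", "+", cbind(starts, starts + lens))
    k <- sample(1:3, 1)
    bounds <- cumsum(lens)
    cuts <- sort(sample(setdiff(seq_len(sum(lens) - 1), bounds), k))
    dl <- diff(sort(unique(c(0, cuts, bounds))))
    ds <- cumsum(c(0, utils::head(dl, -1) + 150))
    der <- gene_model("der", "sp", "s", "+", cbind(ds, ds + dl))
    dd <- compare_gene_models(ref, der)
    expect_equal(nrow(dd$intron_gains), k)
    expect_equal(sort(dd$intron_gains$coding_offset), cuts)
  }
  # inconsistent coding length is an error
  short <- gene_model("x", "sp", "s", "+", cbind(0, 100))
  expect_error(compare_gene_models(fx$gene_models$reference, short),
               "coding length")
})
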