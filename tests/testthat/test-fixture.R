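test_that("the fixture encodes the 21-taxon study system consistently", {
  fx <- tas1r_fixture()
  expect_length(fx$species_tree$tip.label, 21)
  expect_true(all(c("axolotl", "elephant_fish") %in% fx$species_tree$tip.label))
  expect_length(fx$clades, 11)
  expect_setequal(fx$clade_tree$tip.label, fx$clades)
  expect_setequal(colnames(fx$pm$states), fx$clades)
  # every clade has at least one carrier, every species a valid state
  expect_true(all(colSums(fx$pm$states != "absent") >= 1))
  # the bichir repertoire used for the functional assays
  bichir <- colnames(fx$pm$states)[fx$pm$states["bichir", ] == "intact"]
  expect_setequal(bichir, c("TAS1R1", "TAS1R2A", "TAS1R2B", "TAS1R3B",
                            "TAS1R4", "TAS1R8"))
  # the elephant fish repertoire: three T1R6 copies plus 3C and 4
  ef <- fx$pm$states["elephant_fish", ]
  expect_setequal(names(ef)[ef == "intact"], c("TAS1R3C", "TAS1R4", "TAS1R6"))
  expect_equal(unname(fx$pm$copies["elephant_fish", "TAS1R6"]), 3L)
  # the human row: the three mammalian receptors only
  human <- colnames(fx$pm$states)[fx$pm$states["human", ] != "absent"]
  expect_setequal(human, c("TAS1R1", "TAS1R2A", "TAS1R3A"))
  # pseudogene flags: lungfish TAS1R3B, whale shark TAS1R3C
  expect_identical(fx$pm$states["australian_lungfish", "TAS1R3B"], "pseudogene")
  expect_identical(fx$pm$states["whale_shark", "TAS1R3C"], "pseudogene")
  # gene tree and species map are consistent
  expect_setequal(names(fx$species_map), fx$gene_tree$tip.label)
  expect_true(all(fx$species_map %in% fx$species_tree$tip.label))
  # the bony-vertebrate ancestor is the MRCA of bichir and lungfishes
  expect_identical(mrca(fx$species_tree, c("bichir", "african_lungfish")),
                   "osteichthyes")
})

test_that("fixture gene orders reproduce the cluster and flank observations", {
  fx <- tas1r_fixture()
  # side-by-side family clusters in the expected genomes
  for (sp in c("anole_lizard", "axolotl", "african_lungfish", "coelacanth",
               "elephant_fish")) {
    ords <- Filter(function(o) o$species[1] == sp, fx$gene_orders)
    best <- max(vapply(ords, function(o)
      max(c(0, lengths(detect_clusters(o)))), 0))
    expect_gte(best, 2)
  }
  # DVL1 - [cluster] - MXRA8 flanks
  flank_sp <- c("human", "chicken", "axolotl", "african_lungfish",
                "coelacanth", "bichir", "elephant_fish")
  for (g in c("DVL1", "MXRA8")) {
    pres <- adjacency_presence(fx$gene_orders, c(g, "FAMILY_CLUSTER"),
                               collapse_family = TRUE)
    expect_true(all(pres[flank_sp]), label = g)
    expect_false(any(pres[setdiff(names(pres), flank_sp)]))
  }
  # the flank adjacency reaches back to the jawed-vertebrate ancestor, and
  # the five-gene chain is present at the sarcopterygian ancestor
  anc <- ancestral_adjacencies(fx$species_tree, fx$gene_orders,
                               collapse_family = TRUE)
  root_keys <- apply(anc$node_adjacencies[["jawed_vertebrata"]], 1, paste,
                     collapse = "|")
  expect_true("DVL1|FAMILY_CLUSTER" %in% root_keys)
  sarco <- anc$node_adjacencies[["sarcopterygii"]]
  keys <- apply(sarco, 1, paste, collapse = "|")
  for (k in c("ACAP3|PUSL1", "LPAR6|PUSL1", "INTS11|LPAR6", "CPTP|INTS11"))
    expect_true(k %in% keys, label = k)
  # assembling the sarcopterygian set yields the published chain
  paths <- assemble_order(anc, "sarcopterygii")$paths
  flat <- vapply(paths, paste, "", collapse = ">")
  chain <- paste(c("ACAP3", "PUSL1", "LPAR6", "INTS11", "CPTP"), collapse = ">")
  rchain <- paste(rev(c("ACAP3", "PUSL1", "LPAR6", "INTS11", "CPTP")),
                  collapse = ">")
  expect_true(any(grepl(chain, flat, fixed = TRUE) |
                    grepl(rchain, flat, fixed = TRUE)))
})

test_that("fixture upstream panel plants the Oct word in the right lineages", {
  fx <- tas1r_fixture()
  expect_setequal(fx$upstream$truth$species,
                  c("whale_shark", "bamboo_shark", "cloudy_catshark",
                    "elephant_fish", "coelacanth", "bichir", "gecko",
                    "anole_lizard", "bearded_dragon"))
  expect_false("axolotl" %in% fx$upstream$truth$species)
  expect_equal(unique(nchar(as.character(fx$upstream$windows))), 300)
})

test_that("fixture assay panel carries the reported responder structure", {
  fx <- tas1r_fixture()
  expect_equal(nrow(fx$assay$amino_acids), 17)
  expect_equal(sum(fx$assay$amino_acids$essential), 9)
  expect_length(fx$assay$essential_12, 12)
  expect_setequal(fx$assay$responder_amino_acids,
                  c("Arg", "His", "Phe", "Val", "Leu", "Ile"))
  expect_true(all(fx$assay$responder_amino_acids %in%
                    fx$assay$amino_acids$ligand[fx$assay$amino_acids$essential]))
  # six independent experiments with duplicate wells
  tab <- fx$assay$table
  expect_equal(max(tab$experiment), 6)
  expect_equal(max(tab$well), 2)
  expect_true(all(c("T1R1/T1R3B", "T1R2B/T1R3B", "T1R8/T1R4") %in% tab$pair))
})
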