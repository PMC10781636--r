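# Curated TAS1R fixture: a 21-taxon vertebrate species tree (with approximate
# node ages in Ma), the 11-clade family tree, a gene tree expanded from it,
# the species-by-clade presence matrix, gene orders around the family
# cluster, gene models, an upstream-window panel with the Oct word planted in
# its carrier lineages, and a simulated assay panel with the reported
# responder rows planted. Everything is built in code; matrix cells that are
# not directly quotable from published text carry provenance "figure", the
# rest "text". Stochastic components (upstream windows, assay plate) are
# generated with fixed seeds and are therefore deterministic.

.TAS1R_CLADES <- c("TAS1R1", "TAS1R2A", "TAS1R2B", "TAS1R3A", "TAS1R3B",
                   "TAS1R3C", "TAS1R4", "TAS1R5", "TAS1R6", "TAS1R7", "TAS1R8")

.tas1r_species_tree <- function() {
  nw <- paste0(
    "((elephant_fish:420,(whale_shark:250,(bamboo_shark:150,",
    "cloudy_catshark:150)galeoidea:100)selachii:170)chondrichthyes:53,",
    "((bichir:400,(sterlet:360,((spotted_gar:270,bowfin:270)holostei:50,",
    "(zebrafish:230,fugu:230)teleostei:90)neopterygii:40)actinopteri:40)",
    "actinopterygii:35,(coelacanth:420,((african_lungfish:120,",
    "australian_lungfish:120)dipnoi:293,((caecilian:300,(frog:290,",
    "axolotl:290)batrachia:10)amphibia:52,(human:320,((gecko:200,",
    "(anole_lizard:160,bearded_dragon:160)toxicofera:40)squamata:80,",
    "chicken:280)sauropsida:40)amniota:32)tetrapoda:61)rhipidistia:7)",
    "sarcopterygii:15)osteichthyes:38)jawed_vertebrata;")
  read_newick(nw)
}

.tas1r_taxon_groups <- function() {
  c(elephant_fish = "Chondrichthyes", whale_shark = "Chondrichthyes",
    bamboo_shark = "Chondrichthyes", cloudy_catshark = "Chondrichthyes",
    bichir = "Actinopterygii", sterlet = "Actinopterygii",
    spotted_gar = "Actinopterygii", bowfin = "Actinopterygii",
    zebrafish = "Actinopterygii", fugu = "Actinopterygii",
    coelacanth = "Actinistia",
    african_lungfish = "Dipnoi", australian_lungfish = "Dipnoi",
    caecilian = "Amphibia", frog = "Amphibia", axolotl = "Amphibia",
    gecko = "Squamata", anole_lizard = "Squamata", bearded_dragon = "Squamata",
    chicken = "Aves", human = "Mammalia")
}

.tas1r_matrix <- function(species_tree) {
  chond <- c("elephant_fish", "whale_shark", "bamboo_shark", "cloudy_catshark")
  rayfin <- c("bichir", "sterlet", "spotted_gar", "bowfin", "zebrafish", "fugu")
  lungfish <- c("african_lungfish", "australian_lungfish")
  amph <- c("caecilian", "frog", "axolotl")
  squam <- c("gecko", "anole_lizard", "bearded_dragon")
  bony <- c(rayfin, "coelacanth", lungfish, amph, "human", squam, "chicken")
  species <- c(chond, bony)
  states <- matrix("absent", length(species), length(.TAS1R_CLADES),
                   dimnames = list(species, .TAS1R_CLADES))
  copies <- matrix(0L, length(species), length(.TAS1R_CLADES),
                   dimnames = dimnames(states))
  set_ <- function(clade, sp, state = "intact", n = 1L) {
    states[sp, clade] <<- state
    copies[sp, clade] <<- n
  }
  set_("TAS1R1", bony)
  set_("TAS1R2A", c("human", squam, amph, lungfish, "bowfin", "bichir"))
  set_("TAS1R2A", "coelacanth", n = 2L)
  set_("TAS1R2B", c("bichir", "sterlet", "spotted_gar", "bowfin"))
  set_("TAS1R2B", c("zebrafish", "fugu"), n = 2L)
  set_("TAS1R3A", c("human", "chicken", squam, amph, lungfish))
  set_("TAS1R3B", c(rayfin, "coelacanth"))
  set_("TAS1R3B", amph, n = 2L)
  set_("TAS1R3B", lungfish, state = "pseudogene")
  set_("TAS1R3C", chond)
  set_("TAS1R3C", "whale_shark", state = "pseudogene")
  set_("TAS1R4", c(chond, "bichir", "coelacanth", lungfish,
                   "axolotl", "caecilian", squam))
  set_("TAS1R5", c("axolotl", lungfish, "coelacanth"))
  set_("TAS1R6", chond, n = 3L)
  set_("TAS1R7", c("axolotl", squam))
  set_("TAS1R8", c("bichir", lungfish))
  provenance <- matrix("figure", length(species), length(.TAS1R_CLADES),
                       dimnames = dimnames(states))
  text_cells <- rbind(
    cbind("axolotl", c("TAS1R1", "TAS1R2A", "TAS1R3A", "TAS1R3B", "TAS1R4",
                       "TAS1R5", "TAS1R7")),
    cbind("human", c("TAS1R1", "TAS1R2A", "TAS1R3A")),
    cbind("bichir", c("TAS1R1", "TAS1R2A", "TAS1R2B", "TAS1R3B", "TAS1R4",
                      "TAS1R8")),
    cbind("elephant_fish", c("TAS1R3C", "TAS1R4", "TAS1R6")),
    cbind("coelacanth", c("TAS1R2A", "TAS1R3B", "TAS1R4", "TAS1R5")),
    cbind("african_lungfish", c("TAS1R3B", "TAS1R4", "TAS1R5", "TAS1R8")),
    cbind("australian_lungfish", c("TAS1R3A", "TAS1R3B", "TAS1R4", "TAS1R5",
                                   "TAS1R8")),
    cbind("whale_shark", "TAS1R3C"),
    cbind("chicken", "TAS1R3A"))
  provenance[text_cells] <- "text"
  pm <- presence_matrix(states, copies, species_tree)
  pm$provenance <- provenance
  pm
}

# Expand the clade backbone into a gene tree: each clade becomes the species
# subtree over its carriers (with planted within-group and within-species
# duplications), joined by the family backbone.
.tas1r_gene_tree <- function() {
  g <- function(sp, suffix) paste0(sp, "_", suffix)
  chond <- function(suffix)
    sprintf("(%s,(%s,(%s,%s)))", g("elephant_fish", suffix),
            g("whale_shark", suffix), g("bamboo_shark", suffix),
            g("cloudy_catshark", suffix))
  t1 <- paste0("((bichir_TAS1R1,(sterlet_TAS1R1,((spotted_gar_TAS1R1,",
               "bowfin_TAS1R1),(zebrafish_TAS1R1,fugu_TAS1R1)))),",
               "(coelacanth_TAS1R1,((african_lungfish_TAS1R1,",
               "australian_lungfish_TAS1R1),((caecilian_TAS1R1,(frog_TAS1R1,",
               "axolotl_TAS1R1)),(human_TAS1R1,((gecko_TAS1R1,",
               "(anole_lizard_TAS1R1,bearded_dragon_TAS1R1)),",
               "chicken_TAS1R1))))))")
  t2b <- paste0("(bichir_TAS1R2B,(sterlet_TAS1R2B,((spotted_gar_TAS1R2B,",
                "bowfin_TAS1R2B),((zebrafish_TAS1R2B_1,zebrafish_TAS1R2B_2),",
                "(fugu_TAS1R2B_1,fugu_TAS1R2B_2)))))")
  t2a <- paste0("((bichir_TAS1R2A,bowfin_TAS1R2A),((coelacanth_TAS1R2A_1,",
                "coelacanth_TAS1R2A_2),((african_lungfish_TAS1R2A,",
                "australian_lungfish_TAS1R2A),((caecilian_TAS1R2A,",
                "(frog_TAS1R2A,axolotl_TAS1R2A)),(human_TAS1R2A,(gecko_TAS1R2A,",
                "(anole_lizard_TAS1R2A,bearded_dragon_TAS1R2A)))))))")
  t3a <- paste0("((african_lungfish_TAS1R3A,australian_lungfish_TAS1R3A),",
                "((caecilian_TAS1R3A,(frog_TAS1R3A,axolotl_TAS1R3A)),",
                "(human_TAS1R3A,((gecko_TAS1R3A,(anole_lizard_TAS1R3A,",
                "bearded_dragon_TAS1R3A)),chicken_TAS1R3A))))")
  amph3b <- function(k)
    sprintf("(caecilian_TAS1R3B%d,(frog_TAS1R3B%d,axolotl_TAS1R3B%d))",
            k, k, k)
  t3b <- paste0("((bichir_TAS1R3B,(sterlet_TAS1R3B,((spotted_gar_TAS1R3B,",
                "bowfin_TAS1R3B),(zebrafish_TAS1R3B,fugu_TAS1R3B)))),",
                "(coelacanth_TAS1R3B,((african_lungfish_TAS1R3B,",
                "australian_lungfish_TAS1R3B),(", amph3b(1), ",", amph3b(2),
                "))))")
  t3c <- chond("TAS1R3C")
  t4 <- paste0("(", chond("TAS1R4"), ",(bichir_TAS1R4,(coelacanth_TAS1R4,",
               "((african_lungfish_TAS1R4,australian_lungfish_TAS1R4),",
               "((caecilian_TAS1R4,axolotl_TAS1R4),(gecko_TAS1R4,",
               "(anole_lizard_TAS1R4,bearded_dragon_TAS1R4)))))))")
  t5 <- paste0("(coelacanth_TAS1R5,((african_lungfish_TAS1R5,",
               "australian_lungfish_TAS1R5),axolotl_TAS1R5))")
  t6 <- sprintf("(%s,(%s,%s))", chond("TAS1R6_1"), chond("TAS1R6_2"),
                chond("TAS1R6_3"))
  t7 <- paste0("(axolotl_TAS1R7,(gecko_TAS1R7,(anole_lizard_TAS1R7,",
               "bearded_dragon_TAS1R7)))")
  t8 <- paste0("(bichir_TAS1R8,(african_lungfish_TAS1R8,",
               "australian_lungfish_TAS1R8))")
  nw <- sprintf("((((%s,%s),%s),%s),(%s,(%s,((((%s,%s),%s),%s),%s))));",
                t3a, t3b, t3c, t4, t7, t8, t1, t2b, t2a, t5, t6)
  gt <- read_newick(nw)
  species_map <- stats::setNames(
    sub("_TAS1R.*$", "", gt$tip.label), gt$tip.label)
  list(tree = gt, species_map = species_map)
}

.tas1r_clade_representatives <- function() {
  c(human_TAS1R1 = "TAS1R1", human_TAS1R2A = "TAS1R2A",
    bichir_TAS1R2B = "TAS1R2B", human_TAS1R3A = "TAS1R3A",
    coelacanth_TAS1R3B = "TAS1R3B", elephant_fish_TAS1R3C = "TAS1R3C",
    elephant_fish_TAS1R4 = "TAS1R4", coelacanth_TAS1R5 = "TAS1R5",
    elephant_fish_TAS1R6_1 = "TAS1R6", axolotl_TAS1R7 = "TAS1R7",
    bichir_TAS1R8 = "TAS1R8")
}

.tas1r_gene_orders <- function() {
  mk <- function(species, scaffold, symbols)
    gene_order(species, scaffold, symbols)
  list(
    mk("human", "chr1", c("MXRA8", "TAS1R3A", "DVL1", "ACAP3", "PUSL1",
                          "INTS11", "CPTP")),
    mk("chicken", "chr21", c("MXRA8", "TAS1R3A", "TAS1R1", "DVL1", "ACAP3",
                             "PUSL1", "LPAR6", "INTS11", "CPTP")),
    mk("axolotl", "scaf_ax1", c("MXRA8", "TAS1R5", "TAS1R7", "TAS1R4",
                                "TAS1R3A", "TAS1R3B", "TAS1R2A", "TAS1R1",
                                "DVL1", "ACAP3", "PUSL1", "LPAR6", "INTS11",
                                "CPTP")),
    mk("african_lungfish", "scaf_lf1", c("MXRA8", "TAS1R8", "TAS1R5",
                                         "TAS1R4", "TAS1R3B", "TAS1R2A",
                                         "TAS1R1", "DVL1")),
    mk("coelacanth", "scaf_lc1", c("MXRA8", "TAS1R5", "TAS1R4", "TAS1R3B",
                                   "TAS1R2A", "TAS1R1", "DVL1", "ACAP3",
                                   "PUSL1", "LPAR6", "INTS11", "CPTP")),
    mk("bichir", "scaf_pb1", c("MXRA8", "TAS1R8", "TAS1R4", "TAS1R3B",
                               "TAS1R2A", "TAS1R1", "DVL1")),
    mk("elephant_fish", "scaf_cm1", c("MXRA8", "TAS1R4", "TAS1R3C",
                                      "TAS1R6-1", "TAS1R6-2", "TAS1R6-3",
                                      "DVL1")),
    mk("anole_lizard", "scaf_ac1", c("TAS1R3A", "TAS1R4", "TAS1R7",
                                     "TAS1R1", "TAS1R2A")),
    mk("anole_lizard", "scaf_ac2", c("LPAR6", "INTS11", "CPTP")),
    mk("zebrafish", "chr17", c("GENE_A", "TAS1R1", "GENE_B")),
    mk("zebrafish", "chr8", c("GENE_C", "TAS1R2B-1", "TAS1R2B-2", "GENE_D")),
    mk("zebrafish", "chr14", c("GENE_E", "TAS1R3B", "GENE_F")))
}

.tas1r_gene_models <- function() {
  # canonical six-exon receptor gene on the plus strand; derived model with
  # introns gained in exons 3 and 6 (coding lengths conserved)
  ex_ref <- c(253, 145, 912, 204, 246, 800)
  mk_model <- function(id, sp, lens, intron = 500) {
    starts <- cumsum(c(1000, utils::head(lens, -1) + intron))
    gene_model(id, sp, "scaf_fix", "+", cbind(starts, starts + lens))
  }
  ex_der <- c(253, 145, 500, 412, 204, 246, 350, 450)
  list(reference = mk_model("TAS1R_canonical", "bichir", ex_ref),
       derived = mk_model("TAS1R3B_rayfin", "zebrafish", ex_der))
}

.tas1r_upstream_panel <- function() {
  species <- c("whale_shark", "bamboo_shark", "cloudy_catshark",
               "elephant_fish", "bichir", "coelacanth", "axolotl",
               "caecilian", "gecko", "anole_lizard", "bearded_dragon")
  carriers <- c("whale_shark", "bamboo_shark", "cloudy_catshark",
                "elephant_fish", "coelacanth", "bichir", "gecko",
                "anole_lizard", "bearded_dragon")
  simulate_upstream(species, word = "ATGCAAAT", carrier_species = carriers,
                    L = 300, gc = 0.42, strands = "plus", seed = 20231213)
}

.tas1r_assay_panel <- function() {
  # 9 of the 12 fish-essential amino acids are on the tested panel; the 8
  # non-essential tested ones are not named in print, so a standard set is
  # used (synthetic choice, margins preserved)
  aa_essential <- c("Arg", "His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr",
                    "Val")
  aa_nonessential <- c("Ala", "Asn", "Asp", "Gln", "Glu", "Gly", "Pro", "Ser")
  amino_acids <- c(aa_essential, aa_nonessential)
  other <- c("GMP", "IMP", "sucrose", "sucralose")
  pairs <- c("T1R1/T1R3B", "T1R2B/T1R3B", "T1R8/T1R4")
  responders <- data.frame(
    pair = c("T1R1/T1R3B", "T1R1/T1R3B", "T1R2B/T1R3B", "T1R8/T1R4",
             "T1R8/T1R4", "T1R8/T1R4", "T1R8/T1R4", "T1R8/T1R4"),
    ligand = c("Arg", "sucralose", "His", "Phe", "Val", "Leu", "Ile", "GMP"))
  sim <- simulate_assay(pairs, ligands = c(amino_acids, other),
                        effect_rows = responders, delta = 30000, sigma = 5000,
                        n_experiments = 6, n_wells = 2, seed = 20231214)
  essential_12 <- c("Cys", "His", "Ile", "Leu", "Lys", "Met", "Phe", "Arg",
                    "Thr", "Trp", "Tyr", "Val")
  list(table = sim$table, truth = sim$truth,
       amino_acids = data.frame(
         ligand = amino_acids,
         essential = amino_acids %in% essential_12),
       essential_12 = essential_12,
       responder_amino_acids = c("Arg", "His", "Phe", "Val", "Leu", "Ile"))
}

#' The TAS1R study fixture
#'
#' A self-contained encoding of the vertebrate TAS1R gene family study
#' system: 21-taxon dated species tree, the 11-clade family topology, a gene
#' tree expanded over the carrier species, the presence/pseudogene matrix,
#' taxon groups used for clade/subclade cutting, gene orders around the
#' family cluster, canonical/derived gene models, an upstream-window panel
#' with the Oct word ATGCAAAT planted in its carrier lineages, and a
#' simulated assay plate carrying the reported responder rows. The upstream
#' and assay components are generated with fixed seeds and are
#' deterministic.
#'
#' @return A list with elements `species_tree`, `clade_tree`, `gene_tree`,
#'   `species_map`, `clade_labels`, `taxon_groups`, `pm`, `stem_branches`,
#'   `gene_orders`, `gene_models`, `upstream`, `assay`, `clades`.
#' @export
tas1r_fixture <- function() {
  sp <- .tas1r_species_tree()
  ct <- read_newick(paste0(
    "((((TAS1R3A,TAS1R3B),TAS1R3C),TAS1R4),(TAS1R7,(TAS1R8,",
    "((((TAS1R1,TAS1R2B),TAS1R2A),TAS1R5),TAS1R6))));"))
  gt <- .tas1r_gene_tree()
  list(
    species_tree = sp,
    clade_tree = ct,
    gene_tree = gt$tree,
    species_map = gt$species_map,
    clade_labels = .tas1r_clade_representatives(),
    taxon_groups = .tas1r_taxon_groups(),
    pm = .tas1r_matrix(sp),
    stem_branches = c(jawed_vertebrate_ancestor = "jawed_vertebrata",
                      bony_vertebrate_ancestor = "osteichthyes",
                      sarcopterygian_ancestor = "sarcopterygii",
                      tetrapod_stem = "tetrapoda",
                      amniote_stem = "amniota",
                      mammalian_stem = "human"),
    gene_orders = .tas1r_gene_orders(),
    gene_models = .tas1r_gene_models(),
    upstream = .tas1r_upstream_panel(),
    assay = .tas1r_assay_panel(),
    clades = .TAS1R_CLADES)
}
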