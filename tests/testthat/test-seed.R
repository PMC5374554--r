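test_that("seed site strings reproduce the canonical examples", {
  # mature with positions 2-7 = AGUUGG (the miR2910 seed)
  s <- seed_sites("UAGUUGGAGAGGAAUUGAUCG")
  expect_equal(s$site6, "CCAACT")
  expect_equal(s$site7A1, "CCAACTA")
  # mature with positions 2-8 = GGGGACU (the miR2916 seed)
  s2 <- seed_sites("UGGGGACUGUAGAACUCGAA")
  expect_equal(s2$site8, "AGTCCCCA")
  # degenerate A-run
  expect_equal(seed_sites("AAAAAAAAA")$site6, "TTTTTT")
  expect_error(seed_sites("ACGUACGU", id = "short-mir"), "short-mir")
})

test_that("site strings satisfy their structural invariants", {
  set.seed(11)
  for (rep in 1:25) {
    m <- random_dna(sample(19:24, 1))
    s <- seed_sites(m)
    expect_equal(substr(s$site7A1, 1, 6), s$site6)
    expect_equal(substr(s$site8, 1, 7), s$site7m8)
    expect_equal(substr(s$site7m8, 2, 7), s$site6)
    # round trip: reverse-complementing site6 recovers positions 2-7
    expect_equal(revcomp(s$site6), substr(norm_seq(m), 2, 7))
    expect_true(grepl("^[ACGT]+$", s$site8))
  }
})

test_that("U/T and case differences never change a seed string", {
  a <- seed_sites("UAGUUGGAGAGGAAUUGAUCG")
  b <- seed_sites("tagttggagaggaattgatcg")
  expect_identical(unclass(a), unclass(b))
})

test_that("seed matching reports identity pairs with the class hierarchy", {
  plant <- data.frame(
    id = c("pla-1", "pla-2", "pla-3"),
    mature = c("UAGUUGGAGAGGAAUUGAUCG",   # seed AGUUGG, position 8 = A
               "UGGGGACUGUAGAACUCGAA",    # seed GGGGAC, 2-8 GGGGACU
               "UCCCCUUAAGGAGGAAUUGAU"),
    stringsAsFactors = FALSE)
  human <- data.frame(
    id = c("hsa-67", "hsa-28", "hsa-none"),
    mature = c("AAGUUGGCCCCCCCCCCCCCC",   # 2-7 identical to pla-1, 8 differs
               "GGGGGACUCCCCCCCCCCCCC",   # 2-8 identical to pla-2
               "GACGUACGUACGUACGUACGU"),
    stringsAsFactors = FALSE)
  m6 <- match_human(plant, human, class = "6mer")
  expect_setequal(paste(m6$plant_id, m6$human_id),
                  c("pla-1 hsa-67", "pla-2 hsa-28"))
  expect_equal(m6$match_class[m6$plant_id == "pla-1"], "7mer-A1")
  expect_equal(m6$match_class[m6$plant_id == "pla-2"], "8mer")
  # the stronger class list contains the weaker classes
  expect_true(grepl("6mer", m6$classes[m6$plant_id == "pla-2"]))
  expect_true(grepl("7mer-m8", m6$classes[m6$plant_id == "pla-2"]))
  # requesting 8mer keeps only positions 2-8 identity
  m8 <- match_human(plant, human, class = "8mer")
  expect_equal(m8$plant_id, "pla-2")
  # disjoint catalogs produce no matches
  none <- match_human(plant[3, , drop = FALSE],
                      human[3, , drop = FALSE])
  expect_equal(nrow(none), 0)
})

test_that("planted identical-seed pairs are found exactly, per all-pairs scan", {
  set.seed(13)
  n_plant <- 12
  n_human <- 15
  plant <- data.frame(id = sprintf("pla-%02d", 1:n_plant),
                      mature = replicate(n_plant, random_dna(21)),
                      stringsAsFactors = FALSE)
  human <- data.frame(id = sprintf("hsa-%02d", 1:n_human),
                      mature = replicate(n_human, random_dna(22)),
                      stringsAsFactors = FALSE)
  # plant k identical 2-7 seeds at known pairs
  planted <- list(c(2, 4), c(5, 9), c(11, 1))
  for (pr in planted) {
    substr(human$mature[pr[2]], 2, 7) <- substr(plant$mature[pr[1]], 2, 7)
  }
  got <- match_human(plant, human)
  # oracle: all-pairs string comparison on positions 2-7
  want <- expand.grid(p = 1:n_plant, h = 1:n_human)
  want <- want[substr(plant$mature[want$p], 2, 7) ==
                 substr(human$mature[want$h], 2, 7), ]
  expect_setequal(paste(got$plant_id, got$human_id),
                  paste(plant$id[want$p], human$id[want$h]))
  expect_gte(nrow(got), length(planted))
})

test_that("target transfer unions curated lists with provenance", {
  matches <- data.frame(plant_id = c("pla-1", "pla-1"),
                        human_id = c("hsa-a", "hsa-b"),
                        match_class = "7mer-A1", classes = "6mer,7mer-A1",
                        stringsAsFactors = FALSE)
  interactions <- data.frame(
    mirna_id = c("hsa-a", "hsa-a", "hsa-a", "hsa-b", "hsa-b"),
    gene_symbol = c("G1", "G2", "G3", "G2", "G4"),
    stringsAsFactors = FALSE)
  tr <- transfer_targets(matches, interactions)
  expect_setequal(tr$gene_symbol, c("G1", "G2", "G3", "G4"))
  expect_equal(nrow(tr), 4)  # union without duplicates
  expect_equal(tr$source_human[tr$gene_symbol == "G2"], "hsa-a,hsa-b")
  expect_equal(tr$source_human[tr$gene_symbol == "G1"], "hsa-a")
  # single match with three curated targets
  tr1 <- transfer_targets(matches[1, , drop = FALSE], interactions)
  expect_equal(sort(tr1$gene_symbol), c("G1", "G2", "G3"))
  # matched human absent from the table: empty contribution plus warning
  matches2 <- rbind(matches,
                    data.frame(plant_id = "pla-2", human_id = "hsa-miss",
                               match_class = "7mer-A1",
                               classes = "6mer,7mer-A1"))
  expect_warning(tr2 <- transfer_targets(matches2, interactions), "hsa-miss")
  expect_false("pla-2" %in% tr2$plant_id)
})
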