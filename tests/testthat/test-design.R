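test_that("the seed pass reaches CAI 1 and preserves translation", {
  for (seed in 1:5) {
    prot <- random_protein(40, seed)
    rep <- optimize_codons(prot, celegans_codon_table(),
                           design_constraints(forbidden_motifs = character(0),
                                              max_homopolymer = 1000L))
    expect_equal(rep$cds$protein, prot)
    expect_equal(rep$cai, 1.0)
    expect_equal(nrow(rep$residual_violations), 0L)
  }
})

test_that("forbidden motifs are removed on both strands, translation intact", {
  # force the naive optimum to contain GGTCTC (= GGT|CTC, Gly + Leu)
  tab <- tweaked_codon_table(list(GGA = 0.8, GGC = 0.8, GGG = 0.8,
                                  CTA = 0.8, CTG = 0.8, CTT = 0.8,
                                  TTA = 0.8, TTG = 0.8))
  prot <- "MGLGLK"
  naive <- paste(patcraft:::optimal_codon(prot, tab), collapse = "")
  expect_true(grepl("GGTCTC", naive, fixed = TRUE))
  rep <- optimize_codons(prot, tab)
  expect_false(grepl("GGTCTC", rep$cds$dna, fixed = TRUE))
  expect_false(grepl("GAGACC", rep$cds$dna, fixed = TRUE))
  expect_equal(rep$cds$protein, prot)
  expect_equal(nrow(rep$residual_violations), 0L)
  # minimal CAI loss: a single second-best substitution per motif
  expect_true(all(rep$substitutions$cai_loss <= log(1 / 0.8) + 1e-9))
})

test_that("motifs arising on the reverse strand are also violations", {
  # GAGACC on the sense strand = BsaI site on the bottom strand
  tab <- tweaked_codon_table(list(GAA = 0.8, ACA = 0.8, ACG = 0.8,
                                  ACT = 0.8))
  prot <- "METP"  # ATG GAG ACC CCA
  naive <- paste(patcraft:::optimal_codon(prot, tab), collapse = "")
  expect_true(grepl("GAGACC", naive, fixed = TRUE))
  rep <- optimize_codons(prot, tab)
  expect_false(grepl("GAGACC", rep$cds$dna, fixed = TRUE))
  expect_equal(rep$cds$protein, prot)
})

test_that("over-long homopolymers are repaired", {
  # poly-Lys via AAA gives a 12-mer A run
  tab2 <- codon_usage_table(local({
    df <- data.frame(codon = CODONS64, weight = 1)
    df$weight[df$codon == "AAG"] <- 0.62
    df
  }))
  rep <- optimize_codons("KKKK", tab2)
  r <- rle(strsplit(rep$cds$dna, "")[[1]])
  expect_lte(max(r$lengths), 8L)
  expect_equal(rep$cds$protein, "KKKK")
})

test_that("piRNA sites in the naive optimum are designed out", {
  prot <- random_protein(50, 11)
  tab <- celegans_codon_table()
  naive <- coding_sequence(paste(patcraft:::optimal_codon(prot, tab),
                                 collapse = ""))
  # a piRNA whose perfect target sits inside the naive optimum
  d <- derive_plantable_pirna(naive, codon_start = 10L)
  db <- pirna_db(c(toy = d$pirna))
  expect_gte(pirna_score(scan_pirna_sites(naive, db)), 1)
  rep <- optimize_codons(prot, tab, db = db, id = "toy")
  expect_equal(rep$pirna_score, 0)
  expect_gte(rep$cai, 0.9)
  expect_equal(rep$cds$protein, prot)
})

test_that("deplete_pirna is a fixed point on clean input", {
  cds <- random_cds(30, 21)
  db <- gen_toy_pirna_db(2, 22)
  if (pirna_score(scan_pirna_sites(cds, db)) == 0) {
    rep <- deplete_pirna(cds, db)
    expect_identical(rep$cds$dna, cds$dna)
    expect_equal(nrow(rep$substitutions), 0L)
  }
})

test_that("a seed-breakable site is removed in a single substitution", {
  cds <- random_cds(30, 33)
  d <- derive_plantable_pirna(cds, codon_start = 6L)
  db <- pirna_db(c(p1 = d$pirna))
  expect_equal(pirna_score(scan_pirna_sites(cds, db)), 1)
  rep <- deplete_pirna(cds, db)
  expect_equal(rep$pirna_score, 0)
  expect_lte(nrow(rep$substitutions), 1L)
  expect_equal(rep$cds$protein, cds$protein)
})

test_that("depletion is monotone across its substitution trajectory", {
  base <- random_cds(40, 55)
  # three plantable piRNAs targeting disjoint codon-aligned windows; each
  # needs real synonymous recoding to land (twist = TRUE)
  pirs <- vapply(c(2L, 13L, 24L), function(k)
    derive_plantable_pirna(base, k, twist = TRUE)$pirna, "")
  db3 <- pirna_db(stats::setNames(pirs, paste0("p", 1:3)))
  cds <- base
  for (k in 1:3)
    cds <- plant_pirna_site(cds, pirs[k])$cds
  expect_gte(pirna_score(scan_pirna_sites(cds, db3)), 3)
  rep <- deplete_pirna(cds, db3)
  expect_equal(rep$pirna_score, 0)
  # replay the substitutions and check the score never increases
  dna <- cds$dna
  scores <- pirna_score(scan_pirna_sites(dna, db3))
  subs <- rep$substitutions
  for (r in seq_len(nrow(subs))) {
    dna <- patcraft:::apply_substitution(dna, subs$codon_index[r], subs$to[r])
    scores <- c(scores, pirna_score(scan_pirna_sites(dna, db3)))
  }
  expect_true(all(diff(scores) <= 0))
  expect_identical(dna, rep$cds$dna)
})

test_that("a site with no synonymous escape is reported, not forced", {
  # Met/Trp-only CDS: no codon has a synonym
  dna <- "ATGTGGATGTGGATGTGGATG"
  cds <- coding_sequence(dna)
  db <- pirna_db(c(trap = revcomp(dna)))
  expect_equal(pirna_score(scan_pirna_sites(cds, db)), 1)
  rep <- deplete_pirna(cds, db)
  expect_identical(rep$cds$dna, dna)
  expect_equal(nrow(rep$residual_violations), 1L)
  expect_equal(rep$pirna_score, 1)
})

test_that("non-translatable input is rejected", {
  expect_error(optimize_codons("MB1Z"), "translatable")
})
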