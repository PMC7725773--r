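test_that("splice model enforces the GT-AG rule on its consensi", {
  m <- splice_model()
  expect_equal(m$donor_consensus, "GTAAGTTT")
  expect_equal(m$acceptor_consensus, "TTTTCAG")
  expect_error(splice_model(donor_consensus = "CAAGTTT"), "begin GT")
  expect_error(splice_model(acceptor_consensus = "TTTTCAA"), "end AG")
  si <- synthetic_intron(length_bp = 50)
  expect_equal(nchar(si), 50L)
  expect_true(startsWith(si, "GT") && endsWith(si, "AG"))
  expect_error(synthetic_intron(length_bp = 10), "exceed")
})

test_that("intron planning targets AG|G junctions with a short first exon", {
  # ATGAG|GGGG: single AG|G junction at offset 5
  expect_equal(plan_intron_positions("ATGAGGGGG", 1), 5L)

  # no junction before the hard bound -> error
  late <- paste0(strrep("ATG", 120), "AGGGTT")
  expect_error(plan_intron_positions(late, 1), "hard first-exon bound")

  # 867-nt CDS with junctions throughout: first offset within 150 bp
  cds <- paste(rep("AAGGAT", 48), collapse = "")  # AG|G at every 6 bp
  cds <- substr(cds, 1, 867 - 867 %% 3)
  offs <- plan_intron_positions(coding_sequence(substr(cds, 1, 864)), 3)
  expect_lte(offs[1], 150L)
  expect_equal(length(offs), 3L)
  expect_true(all(diff(offs) > 0))

  # deterministic
  expect_identical(offs, plan_intron_positions(coding_sequence(substr(cds, 1, 864)), 3))

  # fallback when no junction exists at all
  expect_warning(o <- plan_intron_positions(strrep("ATG", 20), 1),
                 "falling back")
  expect_true(o >= 1 && o < 60)

  expect_error(plan_intron_positions("ATGAGGGGG", 5), "candidate offsets")
})

test_that("insert_introns annotates GT-AG introns at the requested offsets", {
  cds <- random_cds(40, 12)           # 120 bp
  out <- insert_introns(cds, 48L)
  expect_equal(length(out$sequence), 120L + 50L)
  intr <- out$features[out$features$kind == "intron", ]
  expect_equal(c(intr$start, intr$end), c(48L, 98L))
  iseq <- substr(out$sequence$residues, 49, 98)
  expect_true(startsWith(iseq, "GT") && endsWith(iseq, "AG"))

  # zero introns: identity
  id0 <- insert_introns(cds, integer(0))
  expect_equal(id0$sequence$residues, cds$dna)

  # non-consensus interior gets wrapped
  out2 <- insert_introns(cds, 30L, "CCCCCCCC")
  i2 <- out2$features[out2$features$kind == "intron", ]
  iseq2 <- substr(out2$sequence$residues, i2$start + 1, i2$end)
  expect_true(startsWith(iseq2, "GTAAGTTT") && endsWith(iseq2, "TTTTCAG"))

  expect_error(insert_introns(cds, c(30L, 30L)), "strictly increasing")
  expect_error(insert_introns(cds, 500L), "strictly increasing")
})

test_that("splice inverts insert_introns on random CDS fixtures", {
  for (seed in 1:15) {
    cds <- random_cds(25 + (seed %% 11), seed)
    n_i <- 1 + seed %% 3
    L <- nchar(cds$dna)
    offs <- withr::with_seed(seed, sort(sample(seq_len(L - 1), n_i)))
    g <- insert_introns(cds, as.integer(offs))
    back <- splice(g, allow_internal_stops = TRUE)
    expect_identical(back$dna, cds$dna)
  }
})

test_that("intron interior does not affect the spliced product", {
  cds <- random_cds(30, 99)
  a <- insert_introns(cds, 33L, paste0("GT", strrep("C", 40), "AG"))
  b <- insert_introns(cds, 33L, paste0("GT", strrep("T", 40), "AG"))
  expect_identical(splice(a, TRUE)$dna, splice(b, TRUE)$dna)
})

test_that("dropping an intron annotation shifts the reading frame", {
  cds <- random_cds(30, 7)
  g <- insert_introns(cds, c(21L, 60L))        # two 50-nt introns
  # splice from intron annotations alone (complement of introns)
  introns_only <- construct(g$sequence,
                            g$features[g$features$kind == "intron", ],
                            check_frame = FALSE)
  expect_identical(splice(introns_only, TRUE)$dna, cds$dna)
  # un-annotating one intron leaks its 50 nt into the CDS: frame shift
  one_gone <- construct(g$sequence,
                        g$features[g$features$kind == "intron", ][1, ],
                        check_frame = FALSE)
  expect_error(splice(one_gone, TRUE), "divisible by 3")
})

test_that("splice refuses a non-GT-AG intron", {
  s <- nt_seq(paste0("ATGATG", "CCAAACCCAA", "TGGTAA"))
  con <- construct(s, rbind(feature("exon", 0L, 6L),
                            feature("intron", 6L, 16L),
                            feature("exon", 16L, 22L)),
                   check_frame = FALSE)
  expect_error(splice(con), "GT-AG")
})

test_that("intron_donor validates attached sequences against the registry", {
  expect_error(intron_donor("x", "p", 4, 100, 50), "site")
  d <- intron_donor("smu-1", "pCFJ1358", 1, 296, 156)
  expect_true(is.na(d$recomputed_density))
  seq <- strrep("AAAAAAGCGG", 30)   # wrong length
  expect_error(intron_donor("x", "p", 1, 296, 156, sequence = seq),
               "length")
  d2 <- intron_donor("x", "p", 1, 300, 156, sequence = seq)
  expect_gt(d2$recomputed_density, 100)
})
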