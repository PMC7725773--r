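test_that("nt_seq normalizes case and rejects illegal residues", {
  s <- nt_seq("acgtn", id = "x")
  expect_equal(s$residues, "ACGTN")
  expect_equal(s$topology, "linear")
  expect_equal(length(s), 5L)
  expect_error(nt_seq(""), "empty")
  expect_error(nt_seq("ACGU"), "position 4")
  expect_error(nt_seq("AXGT"), "position 2")
})

test_that("FASTA reading uppercases, preserves order and names positions", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$residues, "ACGT")

  writeLines(c(">x", "ACGU"), f)
  expect_error(read_fasta(f), "position 4")

  writeLines(c(">a", "ACGT", ">b", "GGCC"), f)
  recs <- read_fasta(f)
  expect_equal(vapply(recs, `[[`, "", "id"), c("a", "b"))

  writeLines(character(0), f)
  expect_error(read_fasta(f), "no FASTA records")
})

test_that("FASTA write/read round-trips content", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- list(nt_seq("ACGTACGT", id = "s1"), nt_seq("TTTTAAAA", id = "s2"))
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(lapply(back, `[[`, "residues"), lapply(seqs, `[[`, "residues"))
  expect_equal(lapply(back, `[[`, "id"), lapply(seqs, `[[`, "id"))
})

test_that("construct validates coordinates, overlap and frame", {
  s <- nt_seq(strrep("ACGT", 30), id = "c")
  expect_error(construct(s, feature("exon", 0L, 200L)), "outside")
  expect_error(construct(s, rbind(feature("exon", 0L, 30L),
                                  feature("intron", 20L, 50L))),
               "overlapping")
  expect_error(construct(s, feature("exon", 0L, 10L)), "divisible by 3")
  c1 <- construct(s, rbind(feature("exon", 0L, 30L),
                           feature("intron", 30L, 60L)))
  expect_s3_class(c1, "construct")
  expect_error(construct(s, metadata = list(delivery_form = "magic")))
})

test_that("GenBank round-trip recovers features; CDS joins infer introns", {
  gb <- withr::local_tempfile(fileext = ".gb")
  res <- strrep("ACGTTGCA", 15)            # 120 bp
  writeLines(c(
    "LOCUS       demo 120 bp DNA linear UNK",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(11..40,61..90)",
    "                     /label=\"cds\"",
    "ORIGIN",
    paste0("        1 ", tolower(res)),
    "//"), gb)
  con <- read_construct(gb)
  ex <- con$features[con$features$kind == "exon", ]
  intr <- con$features[con$features$kind == "intron", ]
  expect_equal(nrow(ex), 2L)
  expect_equal(nrow(intr), 1L)
  expect_equal(c(ex$start, ex$end), c(10L, 60L, 40L, 90L))
  expect_equal(c(intr$start, intr$end), c(40L, 60L))

  # zero features
  writeLines(c("LOCUS       bare 8 bp DNA linear UNK", "ORIGIN",
               "        1 acgtacgt", "//"), gb)
  expect_equal(nrow(read_construct(gb)$features), 0L)

  # coordinates beyond sequence
  writeLines(c("LOCUS       bad 8 bp DNA linear UNK",
               "FEATURES             Location/Qualifiers",
               "     promoter        2..50",
               "ORIGIN", "        1 acgtacgt", "//"), gb)
  expect_error(read_construct(gb), "beyond sequence")

  # writer round-trip
  c0 <- construct(nt_seq(res, id = "demo2", topology = "circular"),
                  rbind(feature("promoter", 0L, 10L, label = "P"),
                        feature("exon", 10L, 40L, label = "cds"),
                        feature("intron", 40L, 60L, label = "i1"),
                        feature("exon", 60L, 90L, label = "cds"),
                        feature("three_prime_utr", 90L, 110L),
                        feature("backbone", 110L, 120L)))
  write_construct(c0, gb)
  c1 <- read_construct(gb)
  expect_equal(c1$sequence$residues, res)
  expect_equal(c1$sequence$topology, "circular")
  expect_equal(sort(unique(c1$features$kind)),
               sort(unique(c0$features$kind)))
  expect_equal(c1$features[c1$features$kind == "exon", c("start", "end")],
               c0$features[c0$features$kind == "exon", c("start", "end")],
               ignore_attr = TRUE)
})

test_that("bedGraph export merges equal runs and round-trips", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  tr <- score_track(c(0, 0, 5, 5, 0), "t")
  write_track(tr, f, "bedgraph")
  rows <- read.table(f)
  expect_equal(unname(as.matrix(rows[, 2:4])),
               matrix(c(0, 2, 0, 2, 4, 5, 4, 5, 0), nrow = 3, byrow = TRUE))
  back <- read_track(f)
  expect_equal(back$values, tr$values)

  write_track(score_track(rep(0, 7), "z"), f, "bedgraph")
  expect_equal(nrow(read.table(f)), 1L)
})

test_that("wiggle export is per-base fixedStep and round-trips", {
  f <- withr::local_tempfile(fileext = ".wig")
  tr <- score_track(c(1, 2, 2, 0, 3), "t")
  write_track(tr, f, "wiggle")
  expect_match(readLines(f)[1], "fixedStep .*start=1 step=1")
  expect_equal(read_track(f)$values, tr$values)
})

test_that("coordinate conversion is self-inverse", {
  r <- coords_to_report(c(0L, 10L), c(5L, 20L))
  expect_equal(r$start1, c(1L, 11L))
  expect_equal(r$end1, c(5L, 20L))
  b <- coords_from_report(r$start1, r$end1)
  expect_equal(b$start0, c(0L, 10L))
  expect_equal(b$end0, c(5L, 20L))
})
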