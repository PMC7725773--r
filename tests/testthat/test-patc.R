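test_that("find_at_runs reports maximal runs, broken by N", {
  expect_equal(find_at_runs("AAATTTT", 3)[, 1:3],
               data.frame(start = c(0L, 3L), length = c(3L, 4L),
                          base = c("A", "T")))
  r <- find_at_runs("AANAAA", 3)
  expect_equal(r$start, 3L)
  expect_equal(r$length, 3L)
  expect_equal(nrow(find_at_runs("ACGTACGT", 3)), 0L)
  expect_error(find_at_runs("AAAA", 0), ">= 1")
  # centers
  expect_equal(find_at_runs("AAAA", 3)$center, 1.5)
})

test_that("non-A/T sequence scores zero everywhere", {
  res <- score_patc(strrep("G", 200))
  expect_equal(res$track$values, rep(0, 200))
  expect_length(res$clusters, 0L)
})

test_that("perfect period-10 run array forms one full chain", {
  s <- paste(rep("AAAAAAGCGG", 10), collapse = "")
  res <- score_patc(s)
  expect_length(res$clusters, 1L)
  expect_equal(nrow(res$clusters[[1]]$runs), 10L)
  # chain score matches the exhaustive oracle
  runs <- find_at_runs(s, 3)
  expect_equal(res$clusters[[1]]$chain_score, patc_chain_bruteforce(runs))
  expect_equal(res$clusters[[1]]$chain_score, 60)  # 10 runs at cap 6
  # track is chain score inside the span, zero outside
  sp <- res$clusters[[1]]$span
  expect_true(all(res$track$values[(sp[1] + 1):sp[2]] == 60))
  expect_true(all(res$track$values[-((sp[1] + 1):sp[2])] == 0))
})

test_that("DP equals exhaustive enumeration on seeded fixtures", {
  params <- patc_params()
  for (i in 1:25) {
    s <- gen_random_seq(90, gc_fraction = 0.35, seed = 3000 + i)
    runs <- find_at_runs(s, params$min_run_length)
    if (nrow(runs) > 12L) runs <- runs[1:12, ]
    if (nrow(runs) == 0L) next
    dp <- patcraft:::patc_chain_dp(runs, params)
    expect_equal(max(dp$S), patc_chain_bruteforce(runs, params),
                 info = paste("seed", 3000 + i))
  }
})

test_that("appending an in-phase capped run never decreases the chain score", {
  base <- paste(rep("AAAAAAGCGG", 6), collapse = "")
  for (extra in 1:3) {
    s1 <- paste(rep("AAAAAAGCGG", 6 + extra - 1), collapse = "")
    s2 <- paste(rep("AAAAAAGCGG", 6 + extra), collapse = "")
    m1 <- patc_summary(score_patc(s1))$max_chain_score
    m2 <- patc_summary(score_patc(s2))$max_chain_score
    expect_gte(m2, m1)
  }
})

test_that("enlarging the period tolerance never decreases chain scores", {
  for (i in 1:10) {
    s <- gen_random_seq(150, gc_fraction = 0.35, seed = 4000 + i)
    runs <- find_at_runs(s, 3)
    if (nrow(runs) < 2L) next
    lo <- patc_chain_bruteforce(runs, patc_params(period_tolerance_bp = 1))
    hi <- patc_chain_bruteforce(runs, patc_params(period_tolerance_bp = 2))
    expect_gte(hi, lo)
  }
})

test_that("balanced mode is exactly reverse-complement invariant", {
  for (i in 1:10) {
    s <- gen_random_seq(200, gc_fraction = 0.4, seed = 6000 + i)
    p <- patc_params(mode = "balanced")
    d1 <- mean(score_patc(s, p)$track$values)
    d2 <- mean(score_patc(nt_seq(revcomp(s$residues)), p)$track$values)
    expect_identical(d1, d2)
  }
})

test_that("patc_summary computes density and coverage", {
  sm <- patc_summary(score_track(c(0, 0, 6, 6), "t"))
  expect_equal(sm$density, 3.0)
  expect_equal(sm$covered_fraction, 0.5)
  sm0 <- patc_summary(score_track(rep(0, 10), "t"))
  expect_equal(sm0$density, 0)
  expect_equal(sm0$covered_fraction, 0)
  expect_error(patc_summary(score_track(c(1, 2), "t"), region = c(2, 2)),
               "empty")
  expect_error(patc_summary(score_track(c(1, 2), "t"), region = c(0, 5)))
})

test_that("planted cluster dominates a dinucleotide-shuffle null (fixed seed)", {
  fx <- gen_patc_sequence(length = 400, gc_fraction = 0.5, n_runs = 10,
                          run_length = 6, period = 10, seed = 20201209)
  d_plant <- patc_summary(score_patc(fx$seq), region = fx$span)$density
  d_null <- vapply(1:30, function(i)
    patc_summary(score_patc(dinucleotide_shuffle(fx$seq, seed = 100 + i)),
                 region = fx$span)$density, 0)
  expect_gt(d_plant, 10 * mean(d_null))
})

test_that("scan_windows summarizes one full-sequence track", {
  z <- scan_windows(strrep("G", 300), window = 100, step = 50)
  expect_true(all(z$density == 0))

  # planted cluster at ~100-200: the argmax window overlaps it
  s <- paste0(strrep("G", 100), paste(rep("AAAAAAGCGG", 10), collapse = ""),
              strrep("G", 100))
  w <- scan_windows(s, window = 100, step = 50)
  top <- w[which.max(w$density), ]
  expect_true(top$start < 200 && top$end > 100)

  # conservation over non-overlapping windows
  w2 <- scan_windows(s, window = 100, step = 100)
  total <- sum(score_patc(s)$track$values)
  expect_equal(sum(w2$density * 100), total)

  expect_warning(res <- scan_windows(strrep("G", 50), window = 100),
                 "window longer")
  expect_equal(nrow(res), 1L)
})

test_that("parameter validation rejects degenerate profiles", {
  expect_error(patc_params(period_tolerance_bp = 6), "period_bp / 2")
  expect_error(patc_params(min_run_length = 0))
})

test_that("the donor intron registry is complete and typed", {
  reg <- intron_donor_registry()
  expect_equal(nrow(reg), 13L)
  expect_equal(names(reg),
               c("name", "plasmid", "site", "length_bp", "patc_density",
                 "addgene"))
  expect_true(all(reg$site %in% 1:3))
  # controls are PATC-poor, PATC-rich donors dominate them
  ctl <- reg[grepl("Control", reg$name), ]
  expect_true(all(ctl$patc_density <= 17))
  expect_true(all(reg$patc_density[grepl("^~", reg$name)] >= 365))
})
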