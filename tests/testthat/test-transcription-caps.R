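test_that("virtual digests follow the stated cut conventions", {
  d <- virtual_digest("AAGATCAA", "MboI")
  expect_equal(d$cut_positions, 2L)
  expect_equal(d$fragments, c(2L, 6L))
  # NlaIII cuts after the G of CATG
  d2 <- virtual_digest("AACATGAA", "NlaIII")
  expect_equal(d2$cut_positions, 6L)
  expect_equal(d2$fragments, c(6L, 2L))
  # no site
  d3 <- virtual_digest("AAAAAA", "MboI")
  expect_equal(d3$fragments, 6L)
  expect_error(virtual_digest("", "MboI"), "empty amplicon")
  expect_error(virtual_digest("ACGT", "FooI"), "unknown enzyme")
})

test_that("digest fragments always reconcatenate to the amplicon", {
  set.seed(4)
  for (r in 1:25) {
    amp <- random_dna(sample(50:400, 1), seed = 400 + r)
    for (enz in c("MboI", "NlaIII")) {
      d <- virtual_digest(amp, enz)
      expect_equal(sum(d$fragments), nchar(amp))
      expect_true(all(diff(d$cut_positions) > 0) || length(d$cut_positions) < 2)
    }
  }
})

test_that("CAPS separates the synthetic variants as designed", {
  spec <- fx_spec(); h2 <- fx_h2()
  ampL <- amplicon_sequence(spec, h2[h2$variant_id == "La", ], 42L, "mboi")
  ampS <- amplicon_sequence(spec, h2[h2$variant_id == "S1", ], 42L, "mboi")
  expect_equal(nchar(ampL), 605L)
  expect_length(virtual_digest(ampL, "MboI")$cut_positions, 2L)
  expect_length(virtual_digest(ampS, "MboI")$cut_positions, 1L)
  nlaa <- amplicon_sequence(spec, h2[h2$variant_id == "La", ], 42L, "nlaiii")
  nlas <- amplicon_sequence(spec, h2[h2$variant_id == "Ls", ], 42L, "nlaiii")
  expect_equal(nchar(nlaa), 88L)
  expect_equal(virtual_digest(nlaa, "NlaIII")$n_sites, 0L)
  expect_equal(virtual_digest(nlas, "NlaIII")$n_sites, 1L)
})

test_that("promoter scans match IUPAC semantics and orientation", {
  expect_equal(promoter_scan("TATATATAGGG"), 0L)
  expect_equal(promoter_scan("TATATATGGGG"), 0L)
  expect_length(promoter_scan("TATATATCGGG"), 0L)  # R is A or G only
  expect_length(promoter_scan(revcomp("AATATATATAGGGTT")), 0L)
  expect_error(promoter_scan("ACGT", "TATAX"), "invalid IUPAC")
})

test_that("the tandem annotator counts exact and degenerate arrays", {
  expect_equal(tandem_annotate(strrep("CCTTGGG", 7), "CCTTGGG")$copies, 7L)
  expect_equal(tandem_annotate("AACCTTGGGCCTTGGGAA", "CCTTGGG")$copies, 2L)
  expect_lte(tandem_annotate(random_dna(200, 77), "ACGTACG")$copies, 1L)
  expect_equal(tandem_annotate("ACGT", "ACGTA")$copies, 0L)
  expect_error(tandem_annotate("ACGT", "A"), "length")
  # one mismatch per copy tolerated in approximate mode
  unit <- "ACGTACGTGG"
  c2 <- sub("^A", "T", unit)
  arr <- paste0(unit, c2, unit)
  expect_equal(tandem_annotate(arr, unit)$copies, 1L)
  expect_equal(tandem_annotate(arr, unit, max_mismatch_frac = 0.1)$copies, 3L)
})

test_that("variant proportions and specific transcription are consistent", {
  # trivial arithmetic
  vp <- variant_proportions(c("S1", "S1", "S2", "ambiguous"))
  expect_equal(vp$proportion[vp$variant == "S1"], 2 / 3)
  expect_error(variant_proportions(rep("ambiguous", 3)), "zero called")
  st <- specific_transcription(c(rep("A", 30), rep("B", 70)),
                               c(rep("A", 60), rep("B", 40)), n_boot = 200L,
                               seed = 1L)
  expect_equal(st$ratio[st$variant == "A"], 2, tolerance = 1e-9)
  expect_equal(st$p_D[st$variant == "A"], 0.3)
  # p_D = p_R gives ratio 1 and ns
  st2 <- specific_transcription(rep(c("A", "B"), 50), rep(c("A", "B"), 50),
                                n_boot = 200L, seed = 1L)
  expect_equal(st2$ratio, c(1, 1))
  expect_true(all(st2$tier == "ns"))
})

test_that("simulated transcription recovers the configured multipliers", {
  spec <- fx_spec(); h1 <- fx_h1()
  gd <- simulate_transcriptome_run(spec, h1, "leaf", 3000, seed = 51L,
                                   source = "gdna")
  cd <- simulate_transcriptome_run(spec, h1, "leaf", 3000, seed = 52L,
                                   source = "cdna")
  refs <- region_references(spec, h1, 51L, windows = "mboi")
  # amplicons must share the reference backbone seed
  gd2 <- simulate_transcriptome_run(spec, h1, "leaf", 3000, seed = 61L,
                                    ref_seed = 51L, source = "gdna")
  cd2 <- simulate_transcriptome_run(spec, h1, "leaf", 3000, seed = 62L,
                                    ref_seed = 51L, source = "cdna")
  gda <- assign_reads(gd2$reads, refs, h1, bisulfite = FALSE)
  cda <- assign_reads(cd2$reads, refs, h1, bisulfite = FALSE)
  expect_equal(mean(gda$call == gd2$truth$variant_id), 1)
  st <- specific_transcription(gda, cda, n_boot = 200L, seed = 5L)
  # silenced S4/S5 emit nothing; S2 is the most efficiently transcribed
  expect_equal(st$ratio[st$variant == "S4"], 0)
  expect_equal(st$ratio[st$variant == "S5"], 0)
  expect_equal(st$tier[st$variant == "S4"], "significant")
  expect_gt(st$ratio[st$variant == "S2"], st$ratio[st$variant == "S1"])
  # with all multipliers equal every ratio converges to 1
  he <- h1; he$multiplier <- 1
  cde <- simulate_transcriptome_run(spec, he, "leaf", 10000, seed = 63L,
                                    ref_seed = 51L, source = "cdna")
  gde <- simulate_transcriptome_run(spec, he, "leaf", 10000, seed = 64L,
                                    ref_seed = 51L, source = "gdna")
  ste <- specific_transcription(assign_reads(gde$reads, refs, he, bisulfite = FALSE),
                                assign_reads(cde$reads, refs, he, bisulfite = FALSE),
                                n_boot = 100L, seed = 6L)
  expect_true(all(abs(ste$ratio - 1) < 0.15))
})
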