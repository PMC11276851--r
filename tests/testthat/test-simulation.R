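test_that("methylome marginals converge to the effective rates", {
  sites <- classify_contexts(build_ets2(fx_spec(), canonical_haplotype(fx_spec()),
                                        seed = 42L))
  model <- fx_model()
  # zero rates give an all-zero matrix
  zero <- methylation_model(cg = 0, cwg = 0, ccg = 0, chh = 0,
                            chh_high_range = c(0, 0), chh_low_range = c(0, 0),
                            chh_mid_logrange = c(1e-9, 1e-8), seed = 1L)
  cg_sites <- sites[sites$class == "CG", ][1:5, ]
  expect_true(all(simulate_methylome(zero, cg_sites, "active", "leaf", 50) == 0L))
  # CG frequency recovers the 97.3% generating rate within 3 binomial SEs
  mm <- simulate_methylome(model, cg_sites[1, ], "active", "leaf", 10000,
                           seed = 7L)
  se <- sqrt(0.973 * 0.027 / 10000)
  expect_lt(abs(mean(mm) - 0.973), 3 * se + 1e-12)
  # a +15 point silent CWG offset separates silent from active by ~15 points
  cwg_sites <- sites[sites$class == "CWG", ][1:10, ]
  m_act <- simulate_methylome(model, cwg_sites, "active", "leaf", 4000, seed = 8L)
  m_sil <- simulate_methylome(model, cwg_sites, "silent", "leaf", 4000, seed = 9L)
  expect_equal(mean(m_sil) - mean(m_act), 0.12, tolerance = 0.02)  # clamp at 1
})

test_that("the positional lattice preserves context means and bin fractions", {
  sites <- classify_contexts(build_ets2(fx_spec(), canonical_haplotype(fx_spec()),
                                        seed = 42L))
  model <- fx_model()
  lat <- site_rate_lattice(model, sites)
  atr <- sites$class == "CHH" & sites$subtype %in% c("CAA", "CTA", "CAT")
  keys <- paste0(sites$strand, ":", sites$pos)
  chh_rates <- lat[keys[atr]]
  expect_equal(mean(chh_rates), 0.07, tolerance = 1e-9)
  # bin fractions are exact up to the rounding granularity of the site count
  expect_lt(abs(mean(chh_rates > 0.5) - 0.03), 1 / length(chh_rates) + 1e-9)
  expect_lt(abs(mean(chh_rates < 0.01) - 0.30), 1 / length(chh_rates) + 1e-9)
  ccg_rates <- lat[keys[sites$class == "CCG"]]
  expect_equal(mean(ccg_rates), 0.35, tolerance = 1e-6)
  expect_true(all(lat >= 0 & lat <= 1))
})

test_that("bisulfite chemistry follows its asymmetry", {
  model <- fx_clean_model()
  s <- "ACGTCCAGGTACCGTACGTACATTGGCCAGTACGTACGATCGGTACCATG"
  s <- paste0(s, s, substr(s, 1, 20))  # 120 nt
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  k <- sum(ch == "C")
  # full conversion of an unmethylated molecule: every read-strand C reads T
  set.seed(1)
  r <- bisulfite_read(s, rep(0L, k), model, "+")
  rch <- strsplit(r, "", fixed = TRUE)[[1]]
  expect_true(all(rch[ch == "C"] == "T"))
  # fully methylated, error-free: read equals the reference window
  set.seed(1)
  expect_identical(bisulfite_read(s, rep(1L, k), model, "+"), s)
  # G positions are never altered by conversion
  expect_true(all(rch[ch == "G"] == "G"))
  # minus-strand reads convert the G positions of the plus strand instead
  km <- sum(ch == "G")
  set.seed(1)
  rm_ <- bisulfite_read(s, rep(0L, km), model, "-")
  rmch <- strsplit(rm_, "", fixed = TRUE)[[1]]
  expect_identical(paste(rmch, collapse = ""), gsub("C", "T", revcomp(s)))
  expect_error(bisulfite_read(s, rep(0L, km), model, "-", start = 10L),
               "outside")
})

test_that("bisulfite runs are deterministic, conserved and correctly weighted", {
  spec <- fx_spec()
  h <- fx_h2()[fx_h2()$variant_id %in% c("La", "S1"), ]
  h$weight <- c(0.6, 0.4)
  r1 <- simulate_bisulfite_run(spec, h, fx_model(), "leaf", 2000, seed = 5L)
  r2 <- simulate_bisulfite_run(spec, h, fx_model(), "leaf", 2000, seed = 5L)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  # conservation: one truth row per FASTQ record
  expect_equal(nrow(r1$truth), nrow(r1$reads))
  expect_identical(r1$truth$read_id, r1$reads$read_id)
  # origin counts follow the genome weights within binomial noise
  n_la <- sum(r1$truth$variant_id == "La")
  expect_lt(abs(n_la - 1200), 3 * sqrt(2000 * 0.6 * 0.4) + 1)
  # truth methylation-state vectors match the cytosine counts
  expect_true(all(nchar(r1$truth$meth_states) == r1$truth$n_cytosines))
  r3 <- simulate_bisulfite_run(spec, h, fx_model(), "leaf", 1, seed = 5L)
  expect_equal(nrow(r3$reads), 1L)
  expect_equal(nrow(r3$truth), 1L)
})

test_that("FASTQ and truth files are byte-identical across reruns", {
  spec <- fx_spec()
  h <- fx_h1()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bisulfite_run(spec, h, fx_model(), "leaf", 200, seed = 11L,
                         out_dir = d1)
  simulate_bisulfite_run(spec, h, fx_model(), "leaf", 200, seed = 11L,
                         out_dir = d2)
  for (f in c("reads.fastq", "truth.tsv", "references.fasta", "config.yaml")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), info = f)
  }
  fq <- Biostrings::readDNAStringSet(file.path(d1, "reads.fastq"),
                                     format = "fastq")
  expect_length(fq, 200L)
  expect_true(all(Biostrings::width(fq) == 120L))
})

test_that("transcriptome reads follow weight x multiplier and skip conversion", {
  spec <- fx_spec(); h2 <- fx_h2(); h1 <- fx_h1()
  # por2-like: only La transcribed
  cd <- simulate_transcriptome_run(spec, h2, "leaf", 500, seed = 3L,
                                   source = "cdna")
  expect_true(all(cd$truth$variant_id == "La"))
  # multipliers all equal: transcriptome proportions match genome proportions
  he <- h1; he$multiplier <- 1
  cd2 <- simulate_transcriptome_run(spec, he, "leaf", 8000, seed = 4L,
                                    source = "cdna")
  p <- table(factor(cd2$truth$variant_id, levels = he$variant_id)) / 8000
  expect_equal(as.numeric(p), he$weight, tolerance = 0.03)
  # silent lineage-wide transcription is an error
  hz <- h1; hz$multiplier <- 0
  expect_error(simulate_transcriptome_run(spec, hz, "leaf", 10, seed = 1L),
               "no transcription")
  # reads are unconverted amplicon copies
  amp <- amplicon_sequence(spec, h2[h2$variant_id == "La", ], 3L, "mboi")
  expect_identical(cd$reads$seq[1], amp)
})
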