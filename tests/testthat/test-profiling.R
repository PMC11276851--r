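test_that("per-site proportions are simple C/(C+T) percentages", {
  # hand-built micro-case: 10 reads over one region, plus strand
  refs <- fx_refs1()
  s1 <- substr(build_ets2(fx_spec(), fx_h1()[1, ], seed = 42L), 1, 120)
  base <- gsub("C", "T", s1)  # fully converted, unmethylated S1 read
  ch0 <- strsplit(s1, "", fixed = TRUE)[[1]]
  cpos <- which(ch0 == "C")
  site <- cpos[1]
  reads <- vapply(1:10, function(i) {
    ch <- strsplit(base, "", fixed = TRUE)[[1]]
    if (i <= 8) ch[site] <- "C"  # 8 methylated, 2 unmethylated observations
    paste(ch, collapse = "")
  }, character(1))
  rd <- data.frame(read_id = sprintf("r%02d", 1:10), seq = reads,
                   stringsAsFactors = FALSE)
  asg <- assign_reads(rd, refs, fx_h1())
  expect_true(all(asg$status == "pass"))
  sites <- classify_contexts(build_ets2(fx_spec(), canonical_haplotype(fx_spec()),
                                        seed = 42L))
  prof <- call_site_methylation(asg, rd, refs, sites, group_by = "pooled")
  row <- prof[prof$pos == site - 1L & prof$strand == "+", ]
  expect_equal(row$meth, 8L)
  expect_equal(row$total, 10L)
  expect_equal(row$pct, 80)
})

test_that("profiles recover generating rates and their canonical order", {
  prof <- fx_prof1()
  cs <- context_summary(prof, min_depth = 10L)
  # por1 pools active and 30% silent copies, so CWG sits above its base rate
  expect_equal(cs$mean_pct[cs$context == "CG"], 97.6, tolerance = 0.8)
  expect_equal(cs$mean_pct[cs$context == "CWG"], 91.6, tolerance = 1.6)
  expect_equal(cs$mean_pct[cs$context == "CCG"], 35, tolerance = 4)
  expect_equal(cs$mean_pct[cs$context == "CHH"], 7, tolerance = 1.2)
  expect_true(cs$mean_pct[cs$context == "CG"] > cs$mean_pct[cs$context == "CWG"])
  expect_true(cs$mean_pct[cs$context == "CWG"] > cs$mean_pct[cs$context == "CCG"])
  expect_true(cs$mean_pct[cs$context == "CCG"] > cs$mean_pct[cs$context == "CHH"])
})

test_that("per-site estimates tighten around the truth as depth grows", {
  spec <- fx_spec()
  h <- fx_h1()[fx_h1()$variant_id == "S1", ]; h$weight <- 1
  model <- fx_model()
  err <- vapply(c(600L, 2400L, 9600L), function(n) {
    run <- simulate_bisulfite_run(spec, h, model, "leaf", n, seed = 31L,
                                  ref_seed = 42L)
    asg <- assign_reads(run$reads, fx_refs1(), fx_h1())
    prof <- call_site_methylation(asg, run$reads, fx_refs1(), run$sites,
                                  group_by = "pooled")
    cg <- prof[prof$class == "CG" & prof$total >= 5L, ]
    sqrt(mean((cg$pct - 97.3)^2))
  }, numeric(1))
  expect_true(err[3] < err[1])
  expect_lt(err[3], 2)
})

test_that("strand pooling conserves methylated and total counts", {
  prof <- fx_prof1()
  pooled <- stats::aggregate(cbind(meth, total) ~ class, data = prof, FUN = sum)
  by_strand <- stats::aggregate(cbind(meth, total) ~ class + strand,
                                data = prof, FUN = sum)
  re <- stats::aggregate(cbind(meth, total) ~ class, data = by_strand, FUN = sum)
  expect_equal(pooled, re)
})

test_that("whole-read metrics match their closed forms", {
  run <- fx_run1(); asg <- fx_asg1(); refs <- fx_refs1()
  # all-demethylated CWG fraction: reads with k CWGs are all-T with
  # probability ~ prod(1 - rate_i); compare against the per-region closed form
  pm <- per_read_metrics(asg, run$reads, refs, run$sites, "CWG",
                         group_by = "pooled")
  expect_true(pm$fraction > 0 && pm$fraction < 0.15)
  # CG mode counts reads with >= 1 unmethylated CG
  pg <- per_read_metrics(asg, run$reads, refs, run$sites, "CG",
                         group_by = "pooled")
  expect_true(pg$fraction > 0 && pg$fraction < 1)
  # degenerate cases on a hand-built read set: every CWG methylated
  s1 <- substr(build_ets2(fx_spec(), fx_h1()[1, ], seed = 42L), 1, 120)
  rd <- data.frame(read_id = "r1", seq = s1, stringsAsFactors = FALSE)
  asg1 <- assign_reads(rd, refs, fx_h1())
  pm1 <- per_read_metrics(asg1, rd, refs, run$sites, "CWG", group_by = "pooled")
  expect_equal(pm1$fraction, 0)
  pg1 <- per_read_metrics(asg1, rd, refs, run$sites, "CG", group_by = "pooled")
  expect_equal(pg1$fraction, 0)
})

test_that("all-demethylated fractions follow the independence closed form", {
  # single variant, plus strand only, clean chemistry: the fraction of reads
  # with every CWG unmethylated in a region is prod_i(1 - r_i)
  spec <- fx_spec()
  h <- fx_h1()[fx_h1()$variant_id == "S1", ]; h$weight <- 1
  model <- methylation_model(conversion = 1, inappropriate = 0, seq_error = 0,
                             strand_fraction = 1, seed = 42L)
  run <- simulate_bisulfite_run(spec, h, model, "leaf", 12000, seed = 33L,
                                ref_seed = 42L)
  refs <- fx_refs1()
  asg <- assign_reads(run$reads, refs, h)
  groups <- run$truth$region  # per-region fractions
  pm <- per_read_metrics(asg, run$reads, refs, run$sites, "CWG",
                         groups = groups)
  sites <- run$sites
  snp_pos <- fx_spec()$snps$pos
  for (i in seq_len(nrow(pm))) {
    rg <- pm$group[i]
    w <- fx_spec()$regions[fx_spec()$regions$region == rg, ]
    sv <- sites[sites$strand == "+" & sites$class == "CWG" &
                sites$pos >= w$start & sites$pos < w$end, ]
    sv <- sv[!vapply(sv$pos, function(p) any(snp_pos >= p & snp_pos <= p + 2),
                     logical(1)), ]
    if (nrow(sv) == 0L) next
    expected <- prod(1 - 0.88)^nrow(sv)
    se <- sqrt(max(expected * (1 - expected), 1e-6) / pm$n_reads[i])
    expect_lt(abs(pm$fraction[i] - expected), 4 * se + 0.005)
  }
})

test_that("site-rate histograms use strict bin edges", {
  prof <- data.frame(group = "g", region = "I", strand = "+",
                     pos = 1:4, class = "CHH",
                     subtype = c("CAA", "CAT", "CTA", "CAA"),
                     meth = c(0L, 10L, 5L, 20L), total = rep(20L, 4))
  prof$pct <- 100 * prof$meth / prof$total
  h <- site_rate_histogram(prof, "CHH-AT", min_depth = 10L)
  expect_equal(h$n_sites, 4L)
  expect_equal(h$high, 0.25)       # only the 100% site; 50% goes to mid
  expect_equal(h$low, 0.25)        # only the 0% site
  expect_equal(h$mid, 0.5)
  prof$pct <- 0
  h0 <- site_rate_histogram(prof, "CHH-AT", min_depth = 10L)
  expect_equal(h0$low, 1)
  expect_error(site_rate_histogram(prof[0, ], "CHH-AT"), "no qualifying")
})
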