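# a clean run shared by the assignment tests: error-free chemistry so reads
# are exactly the converted reference
.clean_run <- function() {
  fx_get("clean_run", function() {
    simulate_bisulfite_run(fx_spec(), fx_h2(), fx_clean_model(), "leaf",
                           n_reads = 1500L, seed = 13L, ref_seed = 42L)
  })
}
.clean_asg <- function() {
  fx_get("clean_asg", function() {
    assign_reads(.clean_run()$reads, fx_refs2(), fx_h2())
  })
}

test_that("error-free reads match their true region and strand", {
  run <- .clean_run(); asg <- .clean_asg()
  expect_true(all(asg$status == "pass"))
  expect_identical(asg$region, run$truth$region)
  expect_identical(asg$strand, run$truth$strand)
})

test_that("random reads and ties fail region matching", {
  m <- match_region(random_dna(120, 99L), fx_refs2())
  expect_equal(m$status, "fail-no-region")
  # a duplicated reference makes every perfect match ambiguous
  refs <- fx_refs2()
  refs$dup <- refs$I
  refs$dup$name <- "dup"
  run <- .clean_run()
  i <- which(run$truth$region == "I")[1]
  m2 <- match_region(run$reads$seq[i], refs)
  expect_equal(m2$status, "fail-no-region")
})

test_that("identity filter exempts conversion and SNP alleles only", {
  run <- .clean_run(); asg <- .clean_asg()
  refs <- fx_refs2()
  i <- which(run$truth$region == "III" & run$truth$strand == "+")[1]
  rd <- run$reads$seq[i]
  expect_equal(identity_filter(rd, refs$III, "+"), "pass")
  # one non-SNP, non-cytosine mismatch fails
  ref3 <- refs$III
  ch <- strsplit(rd, "", fixed = TRUE)[[1]]
  refch <- strsplit(ref3$seq, "", fixed = TRUE)[[1]]
  j <- which(refch == "A" & !(seq_along(refch) - 1L) %in% ref3$snps$relpos)[1]
  ch[j] <- "G"
  expect_equal(identity_filter(paste(ch, collapse = ""), ref3, "+"),
               "fail-identity")
  # the alternative allele at a SNP position still passes (SNP exemption):
  # region III carries snp7, G in L and T in S
  ch <- strsplit(rd, "", fixed = TRUE)[[1]]
  rel <- ref3$snps$relpos[ref3$snps$snp_id == "snp7"]
  for (allele in c("G", "T")) {
    ch[rel + 1L] <- allele
    expect_equal(identity_filter(paste(ch, collapse = ""), ref3, "+"), "pass")
  }
})

test_that("variant calls use only conversion-safe SNPs on the read strand", {
  refs <- fx_refs2(); h2 <- fx_h2()
  run <- .clean_run(); asg <- .clean_asg()
  # plus-strand region II read from La: the G>A SNP isolates La
  i <- which(run$truth$region == "II" & run$truth$strand == "+" &
             run$truth$variant_id == "La")[1]
  expect_equal(asg$call[i], "La")
  # the same molecule read on the minus strand can only reach L-group
  j <- which(run$truth$region == "II" & run$truth$strand == "-" &
             run$truth$variant_id == "La")[1]
  expect_equal(asg$call[j], "ambiguous")  # no safe SNP in region II on minus
  # minus-strand region III reads resolve the array but never La vs Ls
  k <- which(run$truth$region == "III" & run$truth$strand == "-" &
             run$truth$variant_id %in% c("La", "Ls"))
  expect_true(all(asg$call[k] == "L-group"))
  # conflicting safe-SNP alleles give ambiguous: S allele at snp1 with L
  # allele at snp2 (both in region I)
  rd <- strsplit(run$reads$seq[which(run$truth$region == "I" &
                                     run$truth$strand == "+" &
                                     run$truth$variant_id == "La")[1]],
                 "", fixed = TRUE)[[1]]
  rel1 <- refs$I$snps$relpos[refs$I$snps$snp_id == "snp1"]
  rd[rel1 + 1L] <- "T"  # S-major allele; snp2 still carries the L allele
  expect_equal(call_variant(paste(rd, collapse = ""), refs$I, h2, "+"),
               "ambiguous")
})

test_that("flipping an unsafe SNP base never changes a minus-strand call", {
  refs <- fx_refs2(); h2 <- fx_h2()
  run <- .clean_run()
  idx <- which(run$truth$region == "I" & run$truth$strand == "-")[1:10]
  rel_unsafe <- refs$I$snps$relpos[refs$I$snps$snp_id == "snp1"]  # unsafe on -
  col <- 120L - rel_unsafe  # read coordinate of the SNP on the minus strand
  for (i in idx) {
    rd <- strsplit(run$reads$seq[i], "", fixed = TRUE)[[1]]
    before <- call_variant(paste(rd, collapse = ""), refs$I, h2, "-")
    rd[col] <- setdiff(c("A", "C", "G", "T"), rd[col])[1]
    after <- call_variant(paste(rd, collapse = ""), refs$I, h2, "-")
    expect_identical(before, after)
  }
})

test_that("assignment counts are conserved and calls are exhaustive", {
  run <- simulate_bisulfite_run(fx_spec(), fx_h2(), fx_model(), "leaf",
                                2000, seed = 29L, ref_seed = 42L)
  asg <- assign_reads(run$reads, fx_refs2(), fx_h2())
  expect_equal(sum(asg$status == "pass") + sum(asg$status == "fail-identity") +
               sum(asg$status == "fail-no-region"), nrow(run$reads))
  expect_true(all(!is.na(asg$call[asg$status == "pass"])))
})

test_that("error-free plus-strand reads always receive their true group", {
  run <- .clean_run(); asg <- .clean_asg()
  plus <- run$truth$strand == "+"
  grp <- substr(run$truth$variant_id, 1L, 1L)
  callgrp <- substr(asg$call, 1L, 1L)  # variant ids and group labels share it
  expect_true(all(asg$call[plus] != "ambiguous"))
  expect_identical(callgrp[plus], grp[plus])
})
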