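#!/usr/bin/env Rscript
# Per-cytosine and per-read methylation profiles of a por1-like bisulfite
# run: context summaries, the AT-rich CHH site-rate histogram and the
# whole-read demethylation metrics.

suppressPackageStartupMessages(library(rdnamethyl))

seed <- 1L
spec <- rdna_unit_spec()
haps <- lineage_haplotypes("por1")
model <- methylation_model(seed = seed)
dir.create("results", showWarnings = FALSE)

run <- simulate_bisulfite_run(spec, haps, model, "leaf", 10000L, seed = seed)
refs <- region_references(spec, haps, seed)
asg <- assign_reads(run$reads, refs, haps)
cat(sprintf("assignment: %d pass, %d fail-identity, %d fail-no-region\n",
            sum(asg$status == "pass"), sum(asg$status == "fail-identity"),
            sum(asg$status == "fail-no-region")))

prof <- call_site_methylation(asg, run$reads, refs, run$sites,
                              group_by = "pooled")
write.table(prof, "results/site_methylation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cs <- context_summary(prof, model$min_depth)
write.table(cs, "results/context_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nmean per-site methylation by context (%):\n")
print(cs, row.names = FALSE)

hist <- site_rate_histogram(prof, "CHH-AT", model$min_depth)
cat(sprintf("\nAT-rich CHH sites: %.1f%% above 50%%, %.1f%% below 1%% (n = %d)\n",
            100 * hist$high, 100 * hist$low, hist$n_sites))

pr <- do.call(rbind, lapply(c("CWG", "CCG", "CAA", "CAT", "CG"), function(ctx) {
  per_read_metrics(asg, run$reads, refs, run$sites, ctx, group_by = "pooled")
}))
write.table(pr, "results/per_read_metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwhole-read metrics (all-demethylated fraction; for CG: >=1 demethylated):\n")
print(pr, row.names = FALSE)
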