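# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, builder(), envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

fx_spec <- function() fx_get("spec", rdna_unit_spec)
fx_h1 <- function() fx_get("h1", function() lineage_haplotypes("por1"))
fx_h2 <- function() fx_get("h2", function() lineage_haplotypes("por2"))
fx_model <- function() fx_get("model", function() methylation_model(seed = 42L))

# error-free chemistry: complete conversion, no inappropriate conversion, no
# sequencing errors
fx_clean_model <- function() {
  fx_get("clean_model", function() {
    methylation_model(conversion = 1, inappropriate = 0, seq_error = 0,
                      seed = 42L)
  })
}

fx_refs1 <- function() {
  fx_get("refs1", function() region_references(fx_spec(), fx_h1(), seed = 42L))
}
fx_refs2 <- function() {
  fx_get("refs2", function() region_references(fx_spec(), fx_h2(), seed = 42L))
}

# one moderate bisulfite run per lineage, reused by profiling tests
fx_run1 <- function() {
  fx_get("run1", function() {
    simulate_bisulfite_run(fx_spec(), fx_h1(), fx_model(), "leaf",
                           n_reads = 4000L, seed = 42L)
  })
}
fx_asg1 <- function() {
  fx_get("asg1", function() assign_reads(fx_run1()$reads, fx_refs1(), fx_h1()))
}
fx_prof1 <- function() {
  fx_get("prof1", function() {
    call_site_methylation(fx_asg1(), fx_run1()$reads, fx_refs1(),
                          fx_run1()$sites, group_by = "pooled")
  })
}

# independent chemistry oracle: enumerate the observable letters of a
# plus-strand allele on a read strand by brute force over methylation state
# and conversion outcome
oracle_observable <- function(allele, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- if (strand == "-") comp[[allele]] else allele
  out <- character(0)
  for (meth in c(0L, 1L)) {
    for (converted in c(FALSE, TRUE)) {
      if (b != "C") out <- c(out, b)
      else if (converted) out <- c(out, "T")
      else out <- c(out, "C")
    }
  }
  sort(unique(out))
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
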