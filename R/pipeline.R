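#' End-to-end simulation and analysis pipeline
#'
#' One reproducible run: simulate bisulfite and amplicon reads for a lineage
#' preset, assign reads, profile methylation per activity class, compute
#' D_s-a comparisons per context, estimate specific transcription, digest the
#' CAPS amplicons, and reconcile estimates against the hidden truth table.
#'
#' @name pipeline
NULL

.default_config <- function() {
  list(lineage = "por2",
       tissues = c("leaf", "root_tip"),
       n_bisulfite_reads = 4000L,
       n_cdna_reads = 2000L,
       n_gdna_reads = 2000L,
       seed = 1L,
       model = list(),
       out_dir = NULL)
}

#' Read and validate a pipeline configuration
#'
#' @param config a list, or the path of a YAML file.
#' @return validated config list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.default_config(), config)
  if (!cfg$lineage %in% c("por1", "por2")) {
    stop("lineage must be 'por1' or 'por2'")
  }
  stopifnot(cfg$n_bisulfite_reads >= 1L, cfg$n_cdna_reads >= 1L,
            cfg$n_gdna_reads >= 1L)
  cfg
}

# collapse variant and group calls to the array level (S vs L); NA for
# ambiguous/unassigned reads
.call_array <- function(calls) {
  out <- rep(NA_character_, length(calls))
  out[!is.na(calls) & startsWith(calls, "S")] <- "S"
  out[!is.na(calls) & startsWith(calls, "L")] <- "L"
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline for one configuration
#'
#' @param config list or YAML path; see [read_run_config()].  Notable fields:
#'   `lineage` preset (`"por1"`: S1-S5 only, S active; `"por2"`: S + L, S
#'   silent), `tissues`, read counts, `seed`, `model` (overrides passed to
#'   [methylation_model()]), `out_dir`.
#' @return report list (also written as `report.json` plus per-table TSVs
#'   when `out_dir` is set): per-tissue context summaries, D_s-a comparison
#'   table, specific-transcription table, digest table, and truth-vs-estimate
#'   reconciliation.
#' @export
run_pipeline <- function(config) {
  cfg <- .stage("config", read_run_config(config))
  spec <- .stage("spec", rdna_unit_spec())
  haps <- .stage("haplotypes", lineage_haplotypes(cfg$lineage))
  model <- .stage("model", do.call(methylation_model,
                                   utils::modifyList(list(seed = cfg$seed),
                                                     cfg$model)))
  refs <- .stage("references",
                 region_references(spec, haps, cfg$seed, windows = "regions"))
  amp_refs <- .stage("references",
                     region_references(spec, haps, cfg$seed, windows = "mboi"))

  summaries <- list(); comparisons <- list(); reconciliation <- list()
  for (ti in seq_along(cfg$tissues)) {
    tissue <- cfg$tissues[ti]
    message("[", tissue, "] simulating ", cfg$n_bisulfite_reads,
            " bisulfite reads")
    run <- .stage("simulate",
                  simulate_bisulfite_run(spec, haps, model, tissue,
                                         cfg$n_bisulfite_reads,
                                         seed = .mix_seed(cfg$seed, 100L + ti),
                                         ref_seed = cfg$seed))
    asg <- .stage("assign", assign_reads(run$reads, refs, haps))
    arr <- .call_array(asg$call)
    prof_arr <- .stage("methylate",
                       call_site_methylation(asg, run$reads, refs, run$sites,
                                             groups = ifelse(is.na(arr),
                                                             "unresolved", arr)))
    summaries[[tissue]] <- context_summary(prof_arr, model$min_depth)
    if (all(c("S", "L") %in% prof_arr$group)) {
      # array-level contrast: in the por2-like lineage S is silenced while the
      # L array is dominated by the transcribed La, so D_s-a = S minus L
      sil <- prof_arr[prof_arr$group == "S", , drop = FALSE]
      acv <- prof_arr[prof_arr$group == "L", , drop = FALSE]
      cmp <- lapply(c("CG", "CWG", "CCG", "CHH"), function(ctx) {
        .stage("compare",
               compare_profiles(sil, acv, ctx, model$min_depth,
                                label = paste0(tissue, ":S_vs_L")))
      })
      comparisons[[tissue]] <- do.call(rbind, cmp)
    }
    tg <- .call_array(run$truth$variant_id)
    pass <- asg$status == "pass"
    reconciliation[[tissue]] <- list(
      n_reads = nrow(run$reads),
      n_pass = sum(pass),
      n_fail_identity = sum(asg$status == "fail-identity"),
      n_fail_no_region = sum(asg$status == "fail-no-region"),
      array_call_accuracy = mean(arr[pass] == tg[pass], na.rm = TRUE),
      array_call_rate = mean(!is.na(arr[pass])))
  }

  message("simulating amplicon reads (gDNA/cDNA)")
  gd <- .stage("transcribe",
               simulate_transcriptome_run(spec, haps, cfg$tissues[1],
                                          cfg$n_gdna_reads,
                                          seed = .mix_seed(cfg$seed, 301L),
                                          ref_seed = cfg$seed, source = "gdna"))
  cd <- .stage("transcribe",
               simulate_transcriptome_run(spec, haps, cfg$tissues[1],
                                          cfg$n_cdna_reads,
                                          seed = .mix_seed(cfg$seed, 302L),
                                          ref_seed = cfg$seed, source = "cdna"))
  gd_asg <- .stage("transcribe",
                   assign_reads(gd$reads, amp_refs, haps, bisulfite = FALSE))
  cd_asg <- .stage("transcribe",
                   assign_reads(cd$reads, amp_refs, haps, bisulfite = FALSE))
  st <- .stage("transcribe",
               specific_transcription(gd_asg, cd_asg,
                                      seed = .mix_seed(cfg$seed, 303L)))

  message("in-silico CAPS digests")
  dig <- list()
  rep_l <- if (any(startsWith(haps$variant_id, "L"))) "La" else NULL
  rep_s <- haps$variant_id[startsWith(haps$variant_id, "S")][1]
  for (v in c(rep_l, rep_s)) {
    h <- haps[haps$variant_id == v, , drop = FALSE]
    mb <- virtual_digest(amplicon_sequence(spec, h, cfg$seed, "mboi"), "MboI")
    nl <- virtual_digest(amplicon_sequence(spec, h, cfg$seed, "nlaiii"), "NlaIII")
    dig[[v]] <- list(MboI_cuts = length(mb$cut_positions),
                     MboI_fragments = mb$fragments_sorted,
                     NlaIII_sites = nl$n_sites,
                     NlaIII_fragments = nl$fragments_sorted)
  }
  if ("Ls" %in% haps$variant_id) {
    h <- haps[haps$variant_id == "Ls", , drop = FALSE]
    nl <- virtual_digest(amplicon_sequence(spec, h, cfg$seed, "nlaiii"), "NlaIII")
    dig[["Ls"]] <- list(NlaIII_sites = nl$n_sites,
                        NlaIII_fragments = nl$fragments_sorted)
  }

  report <- list(
    config = cfg[c("lineage", "tissues", "n_bisulfite_reads", "n_cdna_reads",
                   "n_gdna_reads", "seed")],
    schema_version = "1.0",
    model = model[c("base", "silent_offset", "conversion", "inappropriate",
                    "seq_error", "read_length", "strand_fraction",
                    "min_depth", "seed")],
    methylation_summaries = summaries,
    dsa_comparisons = comparisons,
    specific_transcription = st,
    digests = dig,
    reconciliation = reconciliation)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    utils::write.table(st, file.path(cfg$out_dir, "specific_transcription.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(comparisons) > 0L) {
      utils::write.table(do.call(rbind, comparisons),
                         file.path(cfg$out_dir, "dsa_comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}
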