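#' Bisulfite and transcriptome read simulation
#'
#' Bisulfite chemistry deaminates unmethylated cytosine to uracil (sequenced
#' as T) on the read's own strand only; methylated cytosines are protected
#' and guanines are never touched.  Reads are simulated as exact 120 nt
#' windows aligned to the six ETS2 analysis regions (the mapped,
#' reference-identical read population that per-cytosine profiling operates
#' on), with a hidden truth table recording every molecule's origin and true
#' methylation states.
#'
#' @name read-simulation
NULL

.apply_seq_errors <- function(charmat, rate) {
  if (rate <= 0) return(charmat)
  idx <- which(stats::runif(length(charmat)) < rate)
  if (length(idx) > 0L) {
    cur <- match(charmat[idx], .BASES)
    charmat[idx] <- .BASES[((cur - 1L + sample(1:3, length(idx), replace = TRUE)) %% 4L) + 1L]
  }
  charmat
}

#' Bisulfite-convert one molecule and emit a read
#'
#' On the read strand, each unmethylated C becomes T with probability equal to
#' the conversion efficiency; each methylated C becomes T with the
#' inappropriate-conversion probability; all other bases are unchanged by the
#' chemistry.  Independent substitution errors are applied afterwards.  Draws
#' use the current RNG stream; seed the caller for reproducibility.
#'
#' @param sequence plus-strand reference sequence.
#' @param methylation 0/1 vector over the read strand's cytosines inside the
#'   window, ordered by read coordinate.
#' @param model a `methylation_model`.
#' @param strand `"+"` or `"-"`.
#' @param start 0-based window start (plus-strand coordinates); the window is
#'   `[start, start + read_length)`.
#' @return character scalar: the read as sequenced.
#' @export
bisulfite_read <- function(sequence, methylation, model, strand = c("+", "-"),
                           start = 0L) {
  strand <- match.arg(strand)
  len <- model$read_length
  if (start < 0L || start + len > nchar(sequence)) stop("read window outside sequence")
  win <- substr(sequence, start + 1L, start + len)
  template <- if (strand == "+") win else revcomp(win)
  ch <- strsplit(template, "", fixed = TRUE)[[1]]
  cpos <- which(ch == "C")
  if (length(cpos) != length(methylation)) {
    stop("methylation vector length (", length(methylation),
         ") does not match the ", length(cpos), " cytosines on the read strand")
  }
  u <- stats::runif(length(cpos))
  to_t <- ifelse(methylation == 1L, u < model$inappropriate, u < model$conversion)
  ch[cpos[to_t]] <- "T"
  ch <- .apply_seq_errors(matrix(ch, nrow = 1L), model$seq_error)
  paste(ch, collapse = "")
}

#' Simulate a bisulfite sequencing run over the ETS2 regions
#'
#' Reads are drawn from the haplotypes in proportion to their genome weights,
#' from the plus/minus strand per `model$strand_fraction`, and uniformly over
#' the six 120 nt regions.  Each read's methylation states are drawn from the
#' effective per-site rates of its variant x tissue, then bisulfite-converted
#' and subjected to substitution errors.  Deterministic under a fixed seed.
#'
#' @param spec an `rdna_unit_spec`.
#' @param haplotypes haplotype table (weights sum to 1).
#' @param model a `methylation_model`.
#' @param tissue tissue name.
#' @param n_reads number of reads (>= 1).
#' @param seed integer seed for read sampling, methylation and conversion.
#' @param ref_seed integer seed for the reference backbone (defaults to
#'   `seed`; keep it fixed across samples so they share one reference).
#' @param out_dir optional directory; when given, writes `reads.fastq`
#'   (Phred+33, fixed quality), `truth.tsv`, `references.fasta` (per-variant
#'   ETS2) and `config.yaml`.
#' @return list with `reads` (data.frame read_id, seq), `truth` (data.frame
#'   read_id, variant_id, tissue, strand, region, start, n_cytosines,
#'   meth_states, n_converted), `sites` (canonical site table), `lattice`,
#'   and `files` when written.
#' @export
simulate_bisulfite_run <- function(spec, haplotypes, model, tissue = "leaf",
                                   n_reads, seed, ref_seed = seed,
                                   out_dir = NULL) {
  validate_haplotypes(haplotypes)
  stopifnot(n_reads >= 1L)
  if (model$read_length != 120L) {
    stop("read length must equal the 120 nt region width")
  }
  nv <- nrow(haplotypes)
  ets2 <- vapply(seq_len(nv), function(i) {
    build_ets2(spec, haplotypes[i, , drop = FALSE], seed = ref_seed)
  }, character(1))
  names(ets2) <- haplotypes$variant_id
  sites_by_variant <- lapply(ets2, classify_contexts)
  # canonical sites and lattice are lineage-independent: the same cytosine
  # keeps one generating rate across every sample that shares ref_seed
  cons_sites <- classify_contexts(build_ets2(spec, canonical_haplotype(spec),
                                             seed = ref_seed))
  lattice <- site_rate_lattice(model, cons_sites)

  reads <- character(n_reads)
  truth_list <- vector("list", 0L)
  .with_seed(seed, {
    v_idx <- sample.int(nv, n_reads, replace = TRUE, prob = haplotypes$weight)
    r_idx <- sample.int(nrow(spec$regions), n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE,
                     prob = c(model$strand_fraction, 1 - model$strand_fraction))
    for (v in seq_len(nv)) {
      for (r in seq_len(nrow(spec$regions))) {
        for (s in c("+", "-")) {
          idx <- which(v_idx == v & r_idx == r & strand == s)
          m <- length(idx)
          if (m == 0L) next
          rs <- spec$regions$start[r]; re <- spec$regions$end[r]
          win <- substr(ets2[v], rs + 1L, re)
          template <- if (s == "+") win else revcomp(win)
          sv <- sites_by_variant[[v]]
          sv <- sv[sv$strand == s & sv$pos >= rs & sv$pos < re, , drop = FALSE]
          readpos <- if (s == "+") sv$pos - rs else re - 1L - sv$pos
          o <- order(readpos)
          sv <- sv[o, , drop = FALSE]; readpos <- readpos[o]
          k <- nrow(sv)
          rates <- effective_site_rates(model, sv, haplotypes$activity[v],
                                        tissue, lattice)
          meth <- matrix(stats::rbinom(m * k, 1L, rep(rates, each = m)), nrow = m)
          u <- matrix(stats::runif(m * k), nrow = m)
          to_t <- (meth == 1L & u < model$inappropriate) |
                  (meth == 0L & u < model$conversion)
          charmat <- matrix(strsplit(template, "", fixed = TRUE)[[1]],
                            nrow = m, ncol = model$read_length, byrow = TRUE)
          if (k > 0L) {
            obs <- matrix("C", nrow = m, ncol = k)
            obs[to_t] <- "T"
            charmat[, readpos + 1L] <- obs
          }
          charmat <- .apply_seq_errors(charmat, model$seq_error)
          reads[idx] <- do.call(paste0, as.data.frame(charmat,
                                                       stringsAsFactors = FALSE))
          truth_list[[length(truth_list) + 1L]] <- data.frame(
            ord = idx,
            variant_id = haplotypes$variant_id[v],
            tissue = tissue, strand = s,
            region = spec$regions$region[r], start = rs,
            n_cytosines = k,
            meth_states = if (k > 0L) {
              do.call(paste0, as.data.frame(meth, stringsAsFactors = FALSE))
            } else "",
            n_converted = if (k > 0L) rowSums(to_t) else 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  truth <- do.call(rbind, truth_list)
  truth <- truth[order(truth$ord), , drop = FALSE]
  ids <- sprintf("read_%07d", seq_len(n_reads))
  truth <- data.frame(read_id = ids, truth[, setdiff(names(truth), "ord"),
                                           drop = FALSE],
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  out <- list(reads = data.frame(read_id = ids, seq = reads,
                                 stringsAsFactors = FALSE),
              truth = truth, sites = cons_sites, lattice = lattice,
              tissue = tissue, seed = seed)
  if (!is.null(out_dir)) {
    out$files <- .write_run(out, ets2, model, out_dir)
  }
  out
}

.write_run <- function(run, refs, model, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(out_dir, "reads.fastq")
  dna <- Biostrings::DNAStringSet(run$reads$seq)
  names(dna) <- run$reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(run$reads$seq)))
  Biostrings::writeXStringSet(dna, fq, format = "fastq", qualities = qual)
  tsv <- file.path(out_dir, "truth.tsv")
  utils::write.table(run$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(out_dir, "references.fasta")
  rset <- Biostrings::DNAStringSet(refs)
  Biostrings::writeXStringSet(rset, fa)
  cfg <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(list(seed = run$seed, tissue = run$tissue,
                        n_reads = nrow(run$reads),
                        model = model[setdiff(names(model), "tissue_offset")],
                        tissue_offset = lapply(model$tissue_offset, as.list)),
                   cfg)
  c(fastq = fq, truth = tsv, references = fa, config = cfg)
}

#' Simulate transcriptome (cDNA) or genomic amplicon reads
#'
#' Read origins are drawn with probability proportional to genome weight x
#' specific-transcription multiplier (`source = "cdna"`) or to genome weight
#' alone (`source = "gdna"`).  Reads are the unconverted 605 bp ETS2 amplicon
#' of the origin variant (Sanger-clone-like consensus reads), so every
#' diagnostic SNP is observable and silent variants emit no cDNA reads.
#'
#' @param spec an `rdna_unit_spec`.
#' @param haplotypes haplotype table.
#' @param tissue tissue label (metadata only).
#' @param n_reads number of reads.
#' @param seed integer seed for read sampling.
#' @param ref_seed integer seed for the reference backbone (defaults to
#'   `seed`; must match the seed used for [region_references()]).
#' @param source `"cdna"` (weights x multipliers) or `"gdna"` (weights).
#' @param seq_error per-base substitution error rate (default 0).
#' @param out_dir optional output directory (`reads.fasta`, `truth.tsv`).
#' @return list with `reads`, `truth` (read_id, variant_id, tissue, source).
#' @export
simulate_transcriptome_run <- function(spec, haplotypes, tissue = "leaf",
                                       n_reads, seed, ref_seed = seed,
                                       source = c("cdna", "gdna"),
                                       seq_error = 0, out_dir = NULL) {
  source <- match.arg(source)
  validate_haplotypes(haplotypes)
  stopifnot(n_reads >= 1L)
  if (nrow(haplotypes) == 0L) stop("empty haplotype list")
  w <- if (source == "cdna") haplotypes$weight * haplotypes$multiplier
       else haplotypes$weight
  if (sum(w) <= 0) stop("no transcription: all specific-transcription multipliers are 0")
  amp <- vapply(seq_len(nrow(haplotypes)), function(i) {
    amplicon_sequence(spec, haplotypes[i, , drop = FALSE], ref_seed, "mboi")
  }, character(1))
  reads <- .with_seed(seed, {
    v_idx <- sample.int(nrow(haplotypes), n_reads, replace = TRUE, prob = w / sum(w))
    seqs <- amp[v_idx]
    if (seq_error > 0) {
      seqs <- vapply(seqs, function(s) {
        paste(.apply_seq_errors(matrix(strsplit(s, "", fixed = TRUE)[[1]],
                                       nrow = 1L), seq_error), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    list(v_idx = v_idx, seqs = seqs)
  })
  ids <- sprintf("%s_%07d", source, seq_len(n_reads))
  out <- list(reads = data.frame(read_id = ids, seq = reads$seqs,
                                 stringsAsFactors = FALSE),
              truth = data.frame(read_id = ids,
                                 variant_id = haplotypes$variant_id[reads$v_idx],
                                 tissue = tissue, source = source,
                                 stringsAsFactors = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, paste0(source, "_reads.fasta"))
    dna <- Biostrings::DNAStringSet(out$reads$seq)
    names(dna) <- out$reads$read_id
    Biostrings::writeXStringSet(dna, fa)
    tsv <- file.path(out_dir, paste0(source, "_truth.tsv"))
    utils::write.table(out$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- c(fasta = fa, truth = tsv)
  }
  out
}
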