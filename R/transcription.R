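#' Variant transcription efficiency and in-silico CAPS
#'
#' A variant's specific transcription is the ratio of its proportion among
#' primary-transcript (cDNA) reads to its proportion among genomic (gDNA)
#' reads: 1 means transcription proportional to copy number, 0 means
#' silenced.  CAPS genotyping distinguishes variants by restriction targets
#' created or destroyed by diagnostic SNPs: MboI (GATC, cuts before G) has
#' two targets in the L-type ETS2 amplicon but one in S; NlaIII (CATG, cuts
#' after G) has one target in Ls- and S-rDNA but none in La.
#'
#' @name transcription-caps
NULL

#' Variant proportions among called reads
#'
#' @param assignment data.frame from [assign_reads()] (or a character vector
#'   of calls).  Ambiguous, group-level and unassigned reads are excluded.
#' @param include_groups keep `S-group`/`L-group` calls as categories.
#' @return data.frame: variant, count, proportion.
#' @export
variant_proportions <- function(assignment, include_groups = FALSE) {
  calls <- if (is.data.frame(assignment)) {
    assignment$call[assignment$status == "pass"]
  } else assignment
  calls <- calls[!is.na(calls) & calls != "ambiguous"]
  if (!include_groups) calls <- calls[!calls %in% c("S-group", "L-group")]
  if (length(calls) == 0L) stop("zero called reads")
  tab <- table(calls)
  data.frame(variant = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Specific transcription of each variant with bootstrap support
#'
#' @param gdna_calls,cdna_calls assignment data.frames (or call vectors) for
#'   genomic and transcriptome reads.
#' @param n_boot bootstrap resamples for the percentile CI.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return data.frame per variant: `p_D` (genome proportion), `p_R`
#'   (transcriptome proportion), `ratio` (p_R / p_D; NA with flag
#'   `not_in_genome` when p_D = 0), percentile CI bounds, two-proportion
#'   test `p2`, and `tier`.
#' @export
specific_transcription <- function(gdna_calls, cdna_calls, n_boot = 1000L,
                                   conf = 0.95, seed = 1L) {
  getcalls <- function(x) {
    if (is.data.frame(x)) x <- x$call[x$status == "pass"]
    x[!is.na(x) & !x %in% c("ambiguous", "S-group", "L-group")]
  }
  gd <- getcalls(gdna_calls); cd <- getcalls(cdna_calls)
  if (length(gd) == 0L || length(cd) == 0L) stop("zero called reads")
  variants <- sort(unique(c(gd, cd)))
  p_d <- vapply(variants, function(v) mean(gd == v), numeric(1))
  p_r <- vapply(variants, function(v) mean(cd == v), numeric(1))
  ratio <- ifelse(p_d > 0, p_r / p_d, NA_real_)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      g <- gd[sample.int(length(gd), replace = TRUE)]
      c2 <- cd[sample.int(length(cd), replace = TRUE)]
      vapply(variants, function(v) {
        pd <- mean(g == v)
        if (pd > 0) mean(c2 == v) / pd else NA_real_
      }, numeric(1))
    }, numeric(length(variants)))
  })
  boot <- matrix(boot, nrow = length(variants))
  qs <- apply(boot, 1L, stats::quantile,
              probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  p2 <- vapply(seq_along(variants), function(i) {
    x <- c(sum(cd == variants[i]), sum(gd == variants[i]))
    n <- c(length(cd), length(gd))
    if (p_d[i] == 0 && p_r[i] == 0) return(1)
    suppressWarnings(stats::prop.test(x, n)$p.value)
  }, numeric(1))
  data.frame(variant = variants, p_D = unname(p_d), p_R = unname(p_r),
             ratio = unname(ratio),
             ci_lo = unname(qs[1, ]), ci_hi = unname(qs[2, ]),
             p2 = p2, tier = vapply(p2, .p2_tier, character(1)),
             not_in_genome = unname(p_d) == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

.ENZYMES <- list(
  MboI = list(name = "MboI", site = "GATC", cut_offset = 0L),
  NlaIII = list(name = "NlaIII", site = "CATG", cut_offset = 4L)
)

#' In-silico restriction digest of an amplicon
#'
#' Every exact occurrence of the recognition site on the plus strand is found
#' (overlapping occurrences included) and the amplicon is cut at site start +
#' cut offset; fragment lengths always sum to the amplicon length.
#'
#' @param amplicon character scalar.
#' @param enzyme `"MboI"`, `"NlaIII"`, or a list with `name`, `site`,
#'   `cut_offset`.
#' @return list: enzyme name, site, `cut_positions` (0-based, strictly
#'   increasing), `n_sites`, `fragments` (left to right) and
#'   `fragments_sorted` (gel-style, descending).
#' @export
virtual_digest <- function(amplicon, enzyme = "MboI") {
  if (!is.character(amplicon) || length(amplicon) != 1L || nchar(amplicon) == 0L) {
    stop("empty amplicon")
  }
  if (is.character(enzyme)) {
    if (!enzyme %in% names(.ENZYMES)) stop("unknown enzyme: ", enzyme)
    enzyme <- .ENZYMES[[enzyme]]
  }
  stopifnot(all(c("name", "site", "cut_offset") %in% names(enzyme)))
  L <- nchar(amplicon)
  hits <- gregexpr(paste0("(?=", enzyme$site, ")"), amplicon, perl = TRUE)[[1]]
  starts <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  cuts <- starts + enzyme$cut_offset
  cuts <- sort(unique(cuts[cuts > 0L & cuts < L]))
  frags <- diff(c(0L, cuts, L))
  list(enzyme = enzyme$name, site = enzyme$site,
       cut_positions = cuts, n_sites = length(starts),
       fragments = frags, fragments_sorted = sort(frags, decreasing = TRUE))
}

#' Scan a sequence for an IUPAC motif on the plus strand
#'
#' @param sequence character scalar.
#' @param motif IUPAC motif (default the PolI TIS core `TATATATRGGG`).
#' @return integer vector of 0-based hit positions.
#' @export
promoter_scan <- function(sequence, motif = "TATATATRGGG") {
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", motif)) stop("invalid IUPAC letter in motif")
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence),
                                   fixed = FALSE)
  as.integer(Biostrings::start(hits)) - 1L
}

#' Longest head-to-tail tandem array of a unit
#'
#' Finds the longest run of consecutive unit copies; in approximate mode a
#' copy may differ from the candidate unit by a per-copy Hamming distance up
#' to `max_mismatch_frac` of the unit length (the R156 satellite units are
#' partially degenerated).
#'
#' @param sequence character scalar.
#' @param unit candidate repeat unit (length >= 2).
#' @param max_mismatch_frac per-copy mismatch tolerance (0 = exact).
#' @return list: `start` (0-based start of the maximal array, NA when absent)
#'   and `copies` (0 when the unit does not occur).
#' @export
tandem_annotate <- function(sequence, unit, max_mismatch_frac = 0) {
  n <- nchar(unit)
  if (n < 2L) stop("unit length must be >= 2")
  L <- nchar(sequence)
  if (L < n) return(list(start = NA_integer_, copies = 0L))
  seqch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unitch <- strsplit(unit, "", fixed = TRUE)[[1]]
  starts <- seq_len(L - n + 1L)
  mism <- integer(length(starts))
  for (j in seq_len(n)) mism <- mism + (seqch[starts + j - 1L] != unitch[j])
  ok <- mism <= floor(max_mismatch_frac * n)
  if (!any(ok)) return(list(start = NA_integer_, copies = 0L))
  runlen <- integer(length(starts))
  for (s in rev(seq_along(starts))) {
    if (!ok[s]) next
    nxt <- s + n
    runlen[s] <- 1L + if (nxt <= length(starts)) runlen[nxt] else 0L
  }
  best <- which.max(runlen)
  list(start = as.integer(best - 1L), copies = as.integer(runlen[best]))
}
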