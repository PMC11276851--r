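#' Per-cytosine and per-read methylation metrics
#'
#' Per-site methylation is the percentage of pass-filter reads showing C
#' (protected, i.e. methylated) over C+T observations at that cytosine on the
#' read strand.  Per-read metrics follow the two classic whole-read modes:
#' the fraction of reads whose every overlapped CWG (or CCG, CAA, CAT) reads
#' T ("all demethylated"), and for the nearly saturated CGs the fraction of
#' reads where at least one overlapped CG reads T.  Sites whose trinucleotide
#' context overlaps a diagnostic SNP are excluded so every profiled cytosine
#' exists with an identical context in all variants.
#'
#' @name methylation-profiling
NULL

.excluded_sites <- function(sites, snp_pos) {
  if (length(snp_pos) == 0L) return(rep(FALSE, nrow(sites)))
  lo <- ifelse(sites$strand == "+", sites$pos, sites$pos - 2L)
  hi <- ifelse(sites$strand == "+", sites$pos + 2L, sites$pos)
  vapply(seq_len(nrow(sites)),
         function(i) any(snp_pos >= lo[i] & snp_pos <= hi[i]), logical(1))
}

.profile_groups <- function(assignment, group_by, groups) {
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(assignment))
    return(groups)
  }
  if (group_by == "pooled") rep("pooled", nrow(assignment)) else assignment$call
}

#' Per-site methylation profile from assigned reads
#'
#' @param assignment data.frame from [assign_reads()].
#' @param reads data.frame `read_id`, `seq` matching the assignment.
#' @param refs reference windows from [region_references()] (provides window
#'   coordinates and SNP positions).
#' @param sites canonical site table from [classify_contexts()].
#' @param group_by `"call"` (one profile per variant call) or `"pooled"`.
#' @param groups optional explicit group label per read (overrides
#'   `group_by`), e.g. the truth variant or an activity class.
#' @return data.frame (class `methylation_profile`): `group`, `region`,
#'   `strand`, `pos`, `class`, `subtype`, `meth`, `total`, `pct`
#'   (100 * meth / total, NA at zero depth).
#' @export
call_site_methylation <- function(assignment, reads, refs, sites,
                                  group_by = c("call", "pooled"),
                                  groups = NULL) {
  group_by <- match.arg(group_by)
  stopifnot(identical(assignment$read_id, reads$read_id))
  lab <- .profile_groups(assignment, group_by, groups)
  keep <- assignment$status == "pass"
  assignment <- assignment[keep, , drop = FALSE]
  reads <- reads[keep, , drop = FALSE]
  lab <- lab[keep]
  snp_pos <- unique(unlist(lapply(refs, function(r) r$snps$pos)))
  sites <- sites[sites$class != "indeterminate" &
                 !.excluded_sites(sites, snp_pos), , drop = FALSE]
  out <- list()
  for (g in unique(lab)) {
    for (rg in unique(assignment$region[lab == g])) {
      ref <- refs[[rg]]
      for (s in c("+", "-")) {
        idx <- which(lab == g & assignment$region == rg & assignment$strand == s)
        if (length(idx) == 0L) next
        sv <- sites[sites$strand == s & sites$pos >= ref$start &
                    sites$pos < ref$end, , drop = FALSE]
        if (nrow(sv) == 0L) next
        cols <- if (s == "+") sv$pos - ref$start + 1L else ref$end - sv$pos
        readmat <- matrix(unlist(strsplit(reads$seq[idx], "", fixed = TRUE),
                                 use.names = FALSE),
                          nrow = length(idx), byrow = TRUE)
        obs <- readmat[, cols, drop = FALSE]
        meth <- colSums(obs == "C")
        unmeth <- colSums(obs == "T")
        out[[length(out) + 1L]] <- data.frame(
          group = g, region = rg, strand = s, pos = sv$pos,
          class = sv$class, subtype = sv$subtype,
          meth = meth, total = meth + unmeth,
          stringsAsFactors = FALSE)
      }
    }
  }
  prof <- if (length(out) > 0L) do.call(rbind, out) else {
    data.frame(group = character(0), region = character(0),
               strand = character(0), pos = integer(0), class = character(0),
               subtype = character(0), meth = integer(0), total = integer(0))
  }
  prof$pct <- ifelse(prof$total > 0L, 100 * prof$meth / prof$total, NA_real_)
  rownames(prof) <- NULL
  class(prof) <- c("methylation_profile", class(prof))
  prof
}

.context_rows <- function(profile, context) {
  switch(context,
         CG = profile$class == "CG",
         CWG = profile$class == "CWG",
         CCG = profile$class == "CCG",
         CHH = profile$class == "CHH",
         `CHH-AT` = profile$class == "CHH" &
                    profile$subtype %in% c("CAA", "CTA", "CAT"),
         CAA = profile$subtype %in% "CAA",
         CTA = profile$subtype %in% "CTA",
         CAT = profile$subtype %in% "CAT",
         stop("unknown context: ", context))
}

#' Context-level summary of a methylation profile
#'
#' @param profile a `methylation_profile`.
#' @param min_depth minimum per-site depth for inclusion.
#' @return data.frame: group, context, n_sites, mean_pct, median_pct.
#' @export
context_summary <- function(profile, min_depth = 10L) {
  ctxs <- c("CG", "CWG", "CCG", "CHH", "CHH-AT")
  out <- list()
  for (g in unique(profile$group)) {
    for (ctx in ctxs) {
      rows <- profile[profile$group == g & .context_rows(profile, ctx) &
                      profile$total >= min_depth, , drop = FALSE]
      if (nrow(rows) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        group = g, context = ctx, n_sites = nrow(rows),
        mean_pct = mean(rows$pct), median_pct = stats::median(rows$pct),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Whole-read demethylation metrics
#'
#' For contexts CWG, CCG, CAA, CAT (and CTA): the fraction of reads whose
#' every overlapped site of that context reads T.  For CG: the fraction of
#' reads where at least one overlapped CG reads T.  Only reads overlapping at
#' least one site of the context count.
#'
#' @param assignment,reads,refs,sites as in [call_site_methylation()].
#' @param context one of `"CWG"`, `"CCG"`, `"CAA"`, `"CTA"`, `"CAT"`, `"CG"`.
#' @param group_by,groups as in [call_site_methylation()].
#' @return data.frame: group, context, n_reads, fraction (NA when no read
#'   overlaps a qualifying site).
#' @export
per_read_metrics <- function(assignment, reads, refs, sites,
                             context = c("CWG", "CCG", "CAA", "CTA", "CAT", "CG"),
                             group_by = c("call", "pooled"), groups = NULL) {
  context <- match.arg(context)
  group_by <- match.arg(group_by)
  stopifnot(identical(assignment$read_id, reads$read_id))
  lab <- .profile_groups(assignment, group_by, groups)
  keep <- assignment$status == "pass"
  assignment <- assignment[keep, , drop = FALSE]
  reads <- reads[keep, , drop = FALSE]
  lab <- lab[keep]
  snp_pos <- unique(unlist(lapply(refs, function(r) r$snps$pos)))
  sites <- sites[sites$class != "indeterminate" &
                 !.excluded_sites(sites, snp_pos), , drop = FALSE]
  sel <- if (context == "CG") sites$class == "CG"
         else if (context %in% c("CWG", "CCG")) sites$class == context
         else sites$subtype %in% context
  sites <- sites[sel, , drop = FALSE]
  res <- list()
  for (g in unique(lab)) {
    hit <- 0L; covered <- 0L
    for (rg in unique(assignment$region[lab == g])) {
      ref <- refs[[rg]]
      for (s in c("+", "-")) {
        idx <- which(lab == g & assignment$region == rg & assignment$strand == s)
        if (length(idx) == 0L) next
        sv <- sites[sites$strand == s & sites$pos >= ref$start &
                    sites$pos < ref$end, , drop = FALSE]
        if (nrow(sv) == 0L) next
        cols <- if (s == "+") sv$pos - ref$start + 1L else ref$end - sv$pos
        readmat <- matrix(unlist(strsplit(reads$seq[idx], "", fixed = TRUE),
                                 use.names = FALSE),
                          nrow = length(idx), byrow = TRUE)
        obs <- readmat[, cols, drop = FALSE]
        informative <- rowSums(obs == "C" | obs == "T") > 0L
        covered <- covered + sum(informative)
        if (context == "CG") {
          hit <- hit + sum(informative & rowSums(obs == "T") >= 1L)
        } else {
          hit <- hit + sum(informative & rowSums(obs == "C") == 0L &
                           rowSums(obs == "T") >= 1L)
        }
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      group = g, context = context, n_reads = covered,
      fraction = if (covered > 0L) hit / covered else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Histogram of per-site methylation: highly vs poorly methylated sites
#'
#' Bin edges are strict: a site at exactly 50% (or 1%) falls in the middle
#' bin.
#'
#' @param profile a `methylation_profile`.
#' @param context context selector (see [context_summary()]); `"CHH-AT"`
#'   restricts to the AT-rich CHH subtypes CAA/CTA/CAT.
#' @param min_depth minimum per-site depth.
#' @return list: `high` (fraction of sites > 50%), `low` (< 1%), `mid`,
#'   `n_sites`.
#' @export
site_rate_histogram <- function(profile, context = "CHH-AT", min_depth = 10L) {
  rows <- profile[.context_rows(profile, context) &
                  profile$total >= min_depth, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no qualifying sites for context ", context)
  high <- mean(rows$pct > 50)
  low <- mean(rows$pct < 1)
  list(high = high, low = low, mid = 1 - high - low, n_sites = nrow(rows))
}
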