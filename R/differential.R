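#' Silent-vs-active and positional differential methylation
#'
#' D_s-a is the difference (in percentage points) between the methylation
#' medians (and means) of a silent (lower specific transcriptional activity)
#' and an active rDNA variant, computed over qualifying per-site percentages
#' of one sequence context.  Statistical support uses both the non-parametric
#' Mann-Whitney U test and Student's t test, reported as two-tailed p2 with
#' the conventional tiers: not supported (p2 > 0.05), moderate
#' (0.01 < p2 < 0.05), significant (p2 < 0.01).  Positional variability asks
#' a different question: across biological samples, which pairs of individual
#' cytosines differ — high for AT-rich CHHs and CCGs (position-driven
#' methylation), low for CGs and CWGs (variant-driven methylation).
#'
#' @name differential-methylation
NULL

.qualifying_pct <- function(profile, context, min_depth) {
  rows <- profile[.context_rows(profile, context) &
                  profile$total >= min_depth, , drop = FALSE]
  rows$pct
}

#' D_s-a: silent minus active methylation difference
#'
#' @param profile_silent,profile_active `methylation_profile`s of the silent
#'   and active variant (or pooled activity class).
#' @param context context selector (CG, CWG, CCG, CHH, CHH-AT, CAA, CTA, CAT).
#' @param min_depth minimum per-site depth.
#' @return list: `dsa_median` (median(silent) - median(active), percentage
#'   points), `dsa_mean`, `n_silent`, `n_active`.
#' @export
compute_dsa <- function(profile_silent, profile_active, context,
                        min_depth = 10L) {
  a <- .qualifying_pct(profile_silent, context, min_depth)
  b <- .qualifying_pct(profile_active, context, min_depth)
  if (length(a) == 0L || length(b) == 0L) {
    stop("no qualifying ", context, " sites in one of the profiles")
  }
  list(dsa_median = stats::median(a) - stats::median(b),
       dsa_mean = mean(a) - mean(b),
       n_silent = length(a), n_active = length(b))
}

.p2_tier <- function(p) {
  if (is.na(p)) "ns" else if (p < 0.01) "significant"
  else if (p < 0.05) "moderate" else "ns"
}

.dsa_tier <- function(d) {
  ad <- abs(d)
  if (ad > 10) ">10" else if (ad > 5) "5-10" else "<5"
}

#' Compare two methylation profiles in one context
#'
#' @param profile_a,profile_b profiles to compare; for silent-vs-active
#'   comparisons pass the silent profile first so D_s-a keeps the
#'   conventional sign.
#' @param context context selector.
#' @param min_depth minimum per-site depth.
#' @param label optional pair label.
#' @return one-row data.frame: label, context, site counts, D_s-a median and
#'   mean, `U`, `p2_u`, `t`, `p2_t`, `tier` (from the U test) and `dsa_tier`
#'   (|D_s-a| <5 / 5-10 / >10 points).  With fewer than 3 qualifying sites in
#'   a group the comparison is `ns` with a warning; when both groups are
#'   constant and equal, p2 = 1 by convention.
#' @export
compare_profiles <- function(profile_a, profile_b, context, min_depth = 10L,
                             label = NULL) {
  a <- .qualifying_pct(profile_a, context, min_depth)
  b <- .qualifying_pct(profile_b, context, min_depth)
  if (length(a) == 0L || length(b) == 0L) {
    stop("no qualifying ", context, " sites in one of the profiles")
  }
  d_med <- stats::median(a) - stats::median(b)
  d_mean <- mean(a) - mean(b)
  if (length(a) < 3L || length(b) < 3L) {
    warning("fewer than 3 qualifying sites; comparison reported as ns")
    u <- pu <- tt <- pt <- NA_real_
  } else if (stats::sd(c(a, b)) == 0) {
    u <- length(a) * length(b) / 2; pu <- 1; tt <- 0; pt <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    u <- unname(wt$statistic); pu <- wt$p.value
    tr <- stats::t.test(a, b, var.equal = TRUE)
    tt <- unname(tr$statistic); pt <- tr$p.value
  }
  data.frame(label = if (is.null(label)) paste0("A_vs_B") else label,
             context = context, n_a = length(a), n_b = length(b),
             dsa_median = d_med, dsa_mean = d_mean,
             U = u, p2_u = pu, t = tt, p2_t = pt,
             tier = .p2_tier(pu), dsa_tier = .dsa_tier(d_med),
             stringsAsFactors = FALSE)
}

#' Build a sites x samples percentage matrix from per-sample profiles
#'
#' Keeps the sites of the context that reach `min_depth` in every sample.
#'
#' @param profiles named list of `methylation_profile`s (one group each).
#' @param context context selector.
#' @param min_depth minimum per-site depth.
#' @return numeric matrix, rownames `strand:pos`, one column per sample.
#' @export
site_matrix <- function(profiles, context, min_depth = 10L) {
  keyed <- lapply(profiles, function(p) {
    rows <- p[.context_rows(p, context) & p$total >= min_depth, , drop = FALSE]
    setNames(rows$pct, .site_key(rows$strand, rows$pos))
  })
  common <- Reduce(intersect, lapply(keyed, names))
  if (length(common) < 2L) stop("fewer than 2 sites shared across samples")
  m <- vapply(keyed, function(v) v[common], numeric(length(common)))
  rownames(m) <- common
  m
}

#' Fraction of site pairs with significantly different methylation ranges
#'
#' For every unordered pair of sites within the context, the two sites'
#' per-sample percentage vectors are compared by a Mann-Whitney U test; the
#' returned fraction counts pairs with p2 below `alpha`.
#'
#' @param mat sites x samples matrix from [site_matrix()] (>= 4 samples,
#'   >= 2 sites).
#' @param alpha two-tailed significance threshold (default 0.01).
#' @return list: `fraction`, `n_pairs`, `n_sites`, `n_samples`.
#' @export
positional_variability <- function(mat, alpha = 0.01) {
  if (nrow(mat) < 2L) stop("need at least 2 sites")
  if (ncol(mat) < 4L) stop("need at least 4 samples")
  n <- nrow(mat)
  sig <- 0L; pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pairs <- pairs + 1L
      x <- mat[i, ]; y <- mat[j, ]
      if (stats::sd(c(x, y)) == 0) next
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      if (!is.na(p) && p < alpha) sig <- sig + 1L
    }
  }
  list(fraction = sig / pairs, n_pairs = pairs, n_sites = n,
       n_samples = ncol(mat))
}
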