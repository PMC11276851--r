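#' Generating model for per-molecule cytosine methylation
#'
#' Methylation states are drawn per molecule and site as independent
#' Bernoulli variables whose success probability depends on the site's
#' sequence context, the variant's transcriptional state and the tissue.
#' Context-level generating rates follow the average ETS2 methylation
#' reported for this system: CG 97.3%, CWG 88.0%, CCG 35%, CHH 7%.  CG and
#' CWG are uniform across sites; CCG and AT-rich CHH (CAA/CTA/CAT) rates are
#' position-dependent: each site receives its own rate from a fixed quantile
#' lattice of a target distribution, randomly assigned to positions, so that
#' the across-site mean is seed-stable while individual cytosines differ
#' strongly (the positional effect seen for these motifs).  The AT-rich CHH
#' lattice is a three-component mixture: 3% of sites highly methylated
#' (55-65%), 30% nearly unmethylated (<1%), the remainder log-spread and
#' scaled so the overall CHH mean stays at 7%.
#'
#' Transcriptionally silent variants gain context-specific offsets
#' (+15 points CWG, +1 point CG by default); rapidly dividing tissues
#' (root tips, seedlings) lose a few points of CWG methylation.  Effective
#' rates are clamped to [0, 1].
#'
#' @param cg,cwg,ccg,chh base generating rates per context class.
#' @param silent_offset named numeric, percentage-point offsets (as
#'   proportions) added for silent variants.
#' @param tissue_offset named list of named numerics per tissue.
#' @param chh_high_frac,chh_high_range fraction and rate range of highly
#'   methylated AT-rich CHH sites.
#' @param chh_low_frac,chh_low_range fraction and rate range of poorly
#'   methylated AT-rich CHH sites.
#' @param chh_mid_logrange log-spread range of the remaining AT-rich CHH
#'   sites before rescaling to preserve the CHH mean.
#' @param ccg_shape1,ccg_shape2 Beta shape parameters of the CCG site-rate
#'   distribution (rescaled to mean `ccg`).
#' @param conversion bisulfite conversion efficiency for unmethylated C.
#' @param inappropriate probability a methylated C is read as T.
#' @param seq_error per-base sequencing substitution error rate.
#' @param read_length read length in nt (must equal the 120 nt region width).
#' @param strand_fraction fraction of reads drawn from the plus strand.
#' @param min_depth minimum per-site read depth for summary statistics.
#' @param seed integer seed controlling the positional rate lattices.
#' @return object of class `methylation_model`.
#' @export
methylation_model <- function(cg = 0.973, cwg = 0.880, ccg = 0.35, chh = 0.07,
                              silent_offset = c(CG = 0.01, CWG = 0.15,
                                                CCG = 0, CHH = 0),
                              tissue_offset = list(
                                leaf = c(CG = 0, CWG = 0, CCG = 0, CHH = 0),
                                root_tip = c(CG = 0, CWG = -0.04, CCG = 0, CHH = 0),
                                seedling = c(CG = 0, CWG = -0.05, CCG = 0, CHH = 0)),
                              chh_high_frac = 0.03, chh_high_range = c(0.55, 0.65),
                              chh_low_frac = 0.30, chh_low_range = c(2e-4, 0.0055),
                              chh_mid_logrange = c(0.012, 0.24),
                              ccg_shape1 = 1.4, ccg_shape2 = 2.6,
                              conversion = 0.999, inappropriate = 0.001,
                              seq_error = 0.001, read_length = 120L,
                              strand_fraction = 0.5, min_depth = 10L,
                              seed = 1L) {
  base <- c(CG = cg, CWG = cwg, CCG = ccg, CHH = chh)
  stopifnot(all(base >= 0 & base <= 1),
            conversion >= 0, conversion <= 1,
            inappropriate >= 0, inappropriate <= 1,
            seq_error >= 0, seq_error <= 1,
            strand_fraction >= 0, strand_fraction <= 1,
            chh_high_frac + chh_low_frac <= 1)
  m <- list(base = base, silent_offset = silent_offset,
            tissue_offset = tissue_offset,
            chh_high_frac = chh_high_frac, chh_high_range = chh_high_range,
            chh_low_frac = chh_low_frac, chh_low_range = chh_low_range,
            chh_mid_logrange = chh_mid_logrange,
            ccg_shape1 = ccg_shape1, ccg_shape2 = ccg_shape2,
            conversion = conversion, inappropriate = inappropriate,
            seq_error = seq_error, read_length = as.integer(read_length),
            strand_fraction = strand_fraction, min_depth = as.integer(min_depth),
            seed = as.integer(seed))
  class(m) <- "methylation_model"
  m
}

.site_key <- function(strand, pos) paste0(strand, ":", pos)

.is_at_rich_chh <- function(sites) {
  sites$class == "CHH" & sites$subtype %in% c("CAA", "CTA", "CAT")
}

#' Positional rate lattice for CCG and AT-rich CHH sites
#'
#' Rates are the mid-point quantiles of the target distribution, assigned to
#' site positions in a seeded random order.  The lattice is computed once on
#' a canonical (consensus) site table and keyed by (strand, position), so the
#' same cytosine has the same generating rate in every variant, tissue and
#' sample — position-dependence, not activity-dependence.
#'
#' @param model a `methylation_model`.
#' @param sites site table from [classify_contexts()] for the canonical ETS2.
#' @return named numeric vector, names `strand:pos`.
#' @export
site_rate_lattice <- function(model, sites) {
  out <- numeric(0)
  atr <- sites[.is_at_rich_chh(sites), , drop = FALSE]
  n <- nrow(atr)
  if (n > 0L) {
    n_high <- round(model$chh_high_frac * n)
    n_low <- round(model$chh_low_frac * n)
    n_mid <- n - n_high - n_low
    q <- function(k, lo, hi) if (k == 0L) numeric(0) else lo + (seq_len(k) - 0.5) / k * (hi - lo)
    high <- q(n_high, model$chh_high_range[1], model$chh_high_range[2])
    low <- q(n_low, model$chh_low_range[1], model$chh_low_range[2])
    mid <- exp(q(n_mid, log(model$chh_mid_logrange[1]), log(model$chh_mid_logrange[2])))
    target <- model$base[["CHH"]] * n - sum(high) - sum(low)
    if (n_mid > 0L) {
      if (target <= 0) stop("CHH mixture cannot preserve the context mean")
      mid <- mid * (target / sum(mid))
      if (max(mid) >= 0.5) stop("rescaled mid CHH rates reach the >50% bin")
    }
    rates <- c(high, low, mid)
    perm <- .with_seed(.mix_seed(model$seed, .name_key("chh_lattice")), sample(n))
    out <- c(out, setNames(rates[order(perm)], .site_key(atr$strand, atr$pos)))
  }
  ccg <- sites[sites$class == "CCG", , drop = FALSE]
  nc <- nrow(ccg)
  if (nc > 0L) {
    qs <- stats::qbeta((seq_len(nc) - 0.5) / nc, model$ccg_shape1, model$ccg_shape2)
    qs <- pmin(qs * (model$base[["CCG"]] / mean(qs)), 0.99)
    perm <- .with_seed(.mix_seed(model$seed, .name_key("ccg_lattice")), sample(nc))
    out <- c(out, setNames(qs[order(perm)], .site_key(ccg$strand, ccg$pos)))
  }
  out
}

.tissue_offsets <- function(model, tissue, classes) {
  off <- model$tissue_offset[[tissue]]
  if (is.null(off)) stop("unknown tissue: ", tissue)
  v <- off[classes]
  v[is.na(v)] <- 0
  unname(v)
}

#' Effective per-site generating rates
#'
#' Base (or lattice) rate, plus the silent-variant offset when the variant is
#' silent, plus the tissue offset, clamped to \[0, 1\].  Cytosines with an
#' indeterminate context (truncated window at the sequence end) methylate at
#' the CHH base rate but are excluded from profiling.
#'
#' @param model a `methylation_model`.
#' @param sites site table (rows to score).
#' @param activity `"active"` or `"silent"`.
#' @param tissue tissue name present in `model$tissue_offset`.
#' @param lattice optional lattice from [site_rate_lattice()].
#' @return numeric vector of rates, one per site row.
#' @export
effective_site_rates <- function(model, sites, activity, tissue, lattice = NULL) {
  stopifnot(activity %in% c("active", "silent"))
  cls <- ifelse(sites$class == "indeterminate", "CHH", sites$class)
  r <- unname(model$base[cls])
  if (!is.null(lattice) && length(lattice) > 0L) {
    key <- .site_key(sites$strand, sites$pos)
    hit <- match(key, names(lattice))
    use <- !is.na(hit) & (sites$class == "CCG" | .is_at_rich_chh(sites))
    r[use] <- unname(lattice[hit[use]])
  }
  if (activity == "silent") {
    so <- model$silent_offset[cls]
    so[is.na(so)] <- 0
    r <- r + unname(so)
  }
  r <- r + .tissue_offsets(model, tissue, cls)
  pmin(pmax(r, 0), 1)
}

#' Simulate a per-molecule binary methylation matrix
#'
#' Each molecule x site state is an independent Bernoulli draw at the site's
#' effective rate; the empirical frequency over molecules converges to that
#' rate.
#'
#' @param model a `methylation_model`.
#' @param sites site table.
#' @param activity,tissue variant state and tissue.
#' @param n_molecules number of molecules (rows).
#' @param lattice optional positional lattice.
#' @param seed integer seed.
#' @return integer matrix `n_molecules x nrow(sites)` of 0/1 states.
#' @export
simulate_methylome <- function(model, sites, activity, tissue, n_molecules,
                               lattice = NULL, seed = model$seed) {
  stopifnot(n_molecules >= 1L)
  r <- effective_site_rates(model, sites, activity, tissue, lattice)
  .with_seed(seed, {
    matrix(stats::rbinom(n_molecules * length(r), 1L, rep(r, each = n_molecules)),
           nrow = n_molecules)
  })
}
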