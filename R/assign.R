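#' Assignment of bisulfite and transcriptome reads to rDNA variants
#'
#' Reads are matched ungapped against the ~120 nt ETS2 region references (or
#' CAPS amplicon windows) in both orientations under bisulfite-aware matching:
#' a read T is accepted where the oriented reference has C, because
#' conversion acts on the read's own strand.  Only reads identical to the
#' reference — allowing converted cytosines and any tabulated allele at
#' diagnostic SNP positions — enter methylation analysis.  The originating
#' variant is then called from the SNPs that remain conversion-safe on the
#' read's strand; minus-strand reads cannot resolve La from Ls because the
#' G>A transition reads C>T there.
#'
#' @name read-assignment
NULL

.oriented_ref <- function(ref, orientation) {
  L <- nchar(ref$seq)
  if (orientation == "+") {
    list(chars = strsplit(ref$seq, "", fixed = TRUE)[[1]],
         snp_relpos = ref$snps$relpos,
         alleles = .snp_allele_matrix(ref$snps, complement = FALSE))
  } else {
    list(chars = strsplit(revcomp(ref$seq), "", fixed = TRUE)[[1]],
         snp_relpos = L - 1L - ref$snps$relpos,
         alleles = .snp_allele_matrix(ref$snps, complement = TRUE))
  }
}

# matrix: rows = SNPs of the window, cols = variants, entries = oriented alleles
.snp_allele_matrix <- function(snps, complement = FALSE) {
  vcols <- setdiff(names(snps), c("snp_id", "pos", "relpos"))
  m <- as.matrix(snps[, vcols, drop = FALSE])
  if (complement && length(m) > 0L) m[] <- .COMPLEMENT[m]
  rownames(m) <- snps$snp_id
  m
}

# letters acceptable at each oriented reference position under the identity
# rule: reference base (C also accepts T when bisulfite), SNP positions accept
# every tabulated allele (C alleles also accept T when bisulfite)
.allowed_sets <- function(oref, bisulfite) {
  allowed <- lapply(oref$chars, function(c) {
    if (bisulfite && c == "C") c("C", "T") else c
  })
  if (length(oref$snp_relpos) > 0L) {
    for (i in seq_along(oref$snp_relpos)) {
      als <- unique(oref$alleles[i, ])
      s <- unique(unlist(lapply(als, function(a) {
        if (bisulfite && a == "C") c("C", "T") else a
      })))
      allowed[[oref$snp_relpos[i] + 1L]] <- s
    }
  }
  allowed
}

.mismatch_counts <- function(readmat, allowed) {
  n <- nrow(readmat)
  mism <- integer(n)
  for (j in seq_along(allowed)) {
    ok <- readmat[, j] == allowed[[j]][1]
    for (b in allowed[[j]][-1]) ok <- ok | readmat[, j] == b
    mism <- mism + !ok
  }
  mism
}

#' Assign reads to reference windows and call their variant of origin
#'
#' @param reads data.frame with `read_id` and `seq` (all the same length), or
#'   a character vector of sequences.
#' @param refs reference windows from [region_references()].
#' @param haplotypes haplotype table used for SNP exemptions and calling.
#' @param bisulfite logical; `FALSE` for unconverted (cDNA/gDNA) reads, which
#'   makes every SNP usable and disables C/T equivalence.
#' @param max_mismatch_frac reads whose best ungapped match exceeds this
#'   mismatch fraction are `fail-no-region`.
#' @return data.frame: `read_id`, `region`, `strand`, `status`
#'   (`pass`/`fail-identity`/`fail-no-region`), `call` (variant id, `S-group`,
#'   `L-group`, `ambiguous`, or NA when not pass), `mismatches`.
#' @export
assign_reads <- function(reads, refs, haplotypes, bisulfite = TRUE,
                         max_mismatch_frac = 0.25) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = sprintf("read_%07d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  n <- nrow(reads)
  lens <- nchar(reads$seq)
  if (n == 0L) stop("no reads")
  if (length(unique(lens)) != 1L) stop("reads must share one length")
  L <- lens[1]
  usable <- Filter(function(r) nchar(r$seq) == L, refs)
  if (length(usable) == 0L) stop("no reference window matches the read length")
  readmat <- matrix(unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE),
                    nrow = n, byrow = TRUE)
  combos <- expand.grid(ref = names(usable), orientation = c("+", "-"),
                        stringsAsFactors = FALSE)
  scores <- matrix(NA_integer_, nrow = n, ncol = nrow(combos))
  orefs <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    oref <- .oriented_ref(usable[[combos$ref[k]]], combos$orientation[k])
    orefs[[k]] <- oref
    scores[, k] <- .mismatch_counts(readmat, .allowed_sets(oref, bisulfite))
  }
  best <- max.col(-scores, ties.method = "first")
  bestscore <- scores[cbind(seq_len(n), best)]
  nbest <- rowSums(scores == bestscore)
  status <- rep("pass", n)
  status[bestscore > 0L] <- "fail-identity"
  status[nbest > 1L | bestscore > floor(max_mismatch_frac * L)] <- "fail-no-region"
  region <- ifelse(status == "fail-no-region", NA_character_, combos$ref[best])
  strand <- ifelse(status == "fail-no-region", NA_character_,
                   combos$orientation[best])
  call <- rep(NA_character_, n)
  for (k in seq_len(nrow(combos))) {
    idx <- which(status == "pass" & best == k)
    if (length(idx) == 0L) next
    call[idx] <- .call_variants(readmat[idx, , drop = FALSE], orefs[[k]],
                                combos$orientation[k], haplotypes, bisulfite)
  }
  data.frame(read_id = reads$read_id, region = region, strand = strand,
             status = status, call = call, mismatches = bestscore,
             stringsAsFactors = FALSE)
}

# vectorised variant calling over pass-filter reads of one (window, strand)
.call_variants <- function(readmat, oref, orientation, haplotypes, bisulfite) {
  nv <- nrow(haplotypes)
  n <- nrow(readmat)
  snp_ids <- rownames(oref$alleles)
  plus_alleles <- lapply(snp_ids, function(s) unique(haplotypes[[s]]))
  poly <- lengths(plus_alleles) >= 2L  # monomorphic SNPs carry no information
  if (length(snp_ids) > 0L && bisulfite) {
    safe <- poly & vapply(seq_along(snp_ids), function(i) {
      if (!poly[i]) return(FALSE)
      snp_safe(plus_alleles[[i]], strand = orientation)
    }, logical(1))
  } else {
    safe <- poly
  }
  use <- which(safe)
  # with no usable SNP every haplotype stays consistent; the group rule then
  # yields S-group/L-group for single-group tables and ambiguous for mixed ones
  consistent <- matrix(TRUE, nrow = n, ncol = nv)
  for (i in use) {
    obs <- readmat[, oref$snp_relpos[i] + 1L]
    for (v in seq_len(nv)) {
      a <- oref$alleles[i, haplotypes$variant_id[v]]
      okset <- if (bisulfite && a == "C") c("C", "T") else a
      ok <- obs == okset[1]
      for (b in okset[-1]) ok <- ok | obs == b
      consistent[, v] <- consistent[, v] & ok
    }
  }
  vapply(seq_len(n), function(r) {
    H <- haplotypes$variant_id[consistent[r, ]]
    if (length(H) == 0L) return("ambiguous")
    if (length(H) == 1L) return(H)
    grp <- unique(substr(H, 1L, 1L))
    if (identical(grp, "S")) "S-group" else if (identical(grp, "L")) "L-group"
    else "ambiguous"
  }, character(1))
}

#' Match a single read against the reference windows
#'
#' @param read character scalar.
#' @param refs references from [region_references()].
#' @param bisulfite bisulfite-aware matching.
#' @param max_mismatch_frac see [assign_reads()].
#' @return list with `region`, `strand`, `mismatches`, `status`
#'   (`matched`/`fail-no-region`).
#' @export
match_region <- function(read, refs, bisulfite = TRUE, max_mismatch_frac = 0.25) {
  readmat <- matrix(strsplit(read, "", fixed = TRUE)[[1]], nrow = 1L)
  L <- ncol(readmat)
  usable <- Filter(function(r) nchar(r$seq) == L, refs)
  if (length(usable) == 0L) {
    return(list(region = NA_character_, strand = NA_character_,
                mismatches = NA_integer_, status = "fail-no-region"))
  }
  combos <- expand.grid(ref = names(usable), orientation = c("+", "-"),
                        stringsAsFactors = FALSE)
  sc <- vapply(seq_len(nrow(combos)), function(k) {
    oref <- .oriented_ref(usable[[combos$ref[k]]], combos$orientation[k])
    .mismatch_counts(readmat, .allowed_sets(oref, bisulfite))
  }, integer(1))
  k <- which.min(sc)
  if (sum(sc == sc[k]) > 1L || sc[k] > floor(max_mismatch_frac * L)) {
    return(list(region = NA_character_, strand = NA_character_,
                mismatches = min(sc), status = "fail-no-region"))
  }
  list(region = combos$ref[k], strand = combos$orientation[k],
       mismatches = sc[k], status = "matched")
}

#' Identity filter for a matched read
#'
#' Pass iff the read equals the oriented reference at every position, where
#' reference cytosines on the read strand also accept T (bisulfite
#' conversion) and declared SNP positions accept any tabulated allele.
#'
#' @param read character scalar.
#' @param ref one reference window from [region_references()].
#' @param strand read orientation.
#' @param bisulfite logical.
#' @return `"pass"` or `"fail-identity"`.
#' @export
identity_filter <- function(read, ref, strand = c("+", "-"), bisulfite = TRUE) {
  strand <- match.arg(strand)
  readmat <- matrix(strsplit(read, "", fixed = TRUE)[[1]], nrow = 1L)
  oref <- .oriented_ref(ref, strand)
  if (ncol(readmat) != length(oref$chars)) stop("read/reference length mismatch")
  m <- .mismatch_counts(readmat, .allowed_sets(oref, bisulfite))
  if (m == 0L) "pass" else "fail-identity"
}

#' Call the originating variant of a single pass-filter read
#'
#' Uses only SNPs that are conversion-safe on the read's strand (all SNPs for
#' unconverted reads) and returns the most specific label uniquely consistent
#' with the observed alleles: a variant id, `S-group`/`L-group`, or
#' `ambiguous` on conflict or when no safe SNP is available.
#'
#' @param read character scalar.
#' @param ref one reference window from [region_references()].
#' @param haplotypes haplotype table.
#' @param strand read orientation.
#' @param bisulfite logical.
#' @return character scalar.
#' @export
call_variant <- function(read, ref, haplotypes, strand = c("+", "-"),
                         bisulfite = TRUE) {
  strand <- match.arg(strand)
  readmat <- matrix(strsplit(read, "", fixed = TRUE)[[1]], nrow = 1L)
  oref <- .oriented_ref(ref, strand)
  .call_variants(readmat, oref, strand, haplotypes, bisulfite)
}
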