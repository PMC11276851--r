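#' Cytosine sequence-context classification and bisulfite conversion safety
#'
#' Plant cytosine methylation is stratified by the sequence immediately
#' downstream of the cytosine on its own strand: CG, CHG and CHH (H = A, C or
#' T).  The CHG class is further split into CWG (CAG/CTG, W = A or T) and CCG,
#' which follow distinct maintenance pathways (CMT3 alone vs MET1-primed), and
#' CHH carries the AT-rich subtypes CAA, CTA and CAT preferred by CMT2.
#' All coordinates are 0-based, half-open, on the plus strand, where "plus" is
#' the G-rich strand of the ETS2 spacer.
#'
#' @name cytosine-contexts
NULL

.BASES <- c("A", "C", "G", "T")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#'
#' @param x character scalar (A/C/G/T/N).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.class_from_tri <- function(b2, b3) {
  # b2, b3: 2nd and 3rd base of the read-strand trinucleotide (1st is C).
  # NA b2/b3 marks a truncated window at the sequence end.
  cls <- rep("indeterminate", length(b2))
  known <- !is.na(b2)
  cls[known & b2 == "G"] <- "CG"
  hg <- known & b2 != "G" & !is.na(b3) & b3 == "G"
  cls[hg & b2 %in% c("A", "T")] <- "CWG"
  cls[hg & b2 == "C"] <- "CCG"
  hh <- known & b2 != "G" & !is.na(b3) & b3 != "G"
  cls[hh] <- "CHH"
  cls
}

.subtype_from_tri <- function(cls, tri) {
  sub <- rep(NA_character_, length(cls))
  sub[cls == "CWG"] <- tri[cls == "CWG"]            # CAG or CTG
  sub[cls == "CCG"] <- "CCG"
  is_chh <- cls == "CHH"
  sub[is_chh] <- ifelse(tri[is_chh] %in% c("CAA", "CTA", "CAT"),
                        tri[is_chh], "CHH-other")
  sub
}

#' Classify every cytosine of a sequence on both strands
#'
#' Cytosines whose two downstream bases fall off the end of the sequence are
#' labelled `indeterminate` and are excluded from methylation profiling.
#'
#' @param sequence character scalar, plus-strand sequence.
#' @return data.frame with columns `pos` (0-based plus-strand coordinate of the
#'   cytosine), `strand` (`"+"`/`"-"`), `class` (CG/CWG/CCG/CHH/indeterminate),
#'   `subtype` (CAG, CTG, CCG, CAA, CTA, CAT, CHH-other or NA) and `tri`
#'   (read-strand trinucleotide, possibly truncated).
#' @export
classify_contexts <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  at <- function(i) ifelse(i >= 1L & i <= n, ch[pmin(pmax(i, 1L), n)], NA_character_)

  # plus strand: cytosines read left-to-right
  p <- which(ch == "C")
  b2p <- at(p + 1L); b3p <- at(p + 2L)
  clsp <- .class_from_tri(b2p, b3p)
  trip <- if (length(p)) {
    paste0("C", ifelse(is.na(b2p), "", b2p), ifelse(is.na(b3p), "", b3p))
  } else character(0)
  plus <- data.frame(pos = p - 1L, strand = rep("+", length(p)), class = clsp,
                     subtype = .subtype_from_tri(clsp, trip), tri = trip,
                     stringsAsFactors = FALSE)

  # minus strand: a plus-strand G is a minus-strand C; its downstream bases are
  # the complements of the plus-strand bases immediately to its left
  m <- which(ch == "G")
  b2m <- unname(.COMPLEMENT[at(m - 1L)]); b3m <- unname(.COMPLEMENT[at(m - 2L)])
  clsm <- .class_from_tri(b2m, b3m)
  trim <- if (length(m)) {
    paste0("C", ifelse(is.na(b2m), "", b2m), ifelse(is.na(b3m), "", b3m))
  } else character(0)
  minus <- data.frame(pos = m - 1L, strand = rep("-", length(m)), class = clsm,
                      subtype = .subtype_from_tri(clsm, trim), tri = trim,
                      stringsAsFactors = FALSE)

  out <- rbind(plus, minus)
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a single cytosine
#'
#' @param sequence plus-strand sequence.
#' @param position 0-based plus-strand coordinate.
#' @param strand `"+"` or `"-"`.
#' @return one-row data.frame as in [classify_contexts()].
#' @export
classify_context <- function(sequence, position, strand = c("+", "-")) {
  strand <- match.arg(strand)
  ch <- substr(sequence, position + 1L, position + 1L)
  base <- if (strand == "+") ch else unname(.COMPLEMENT[ch])
  if (!identical(base, "C")) {
    stop("base at position ", position, " on strand ", strand, " is not a cytosine")
  }
  sites <- classify_contexts(sequence)
  sites[sites$pos == position & sites$strand == strand, , drop = FALSE]
}

#' Observable letters of an allele after bisulfite conversion
#'
#' On the read strand, a cytosine may be sequenced as C (methylated or
#' unconverted) or T (converted); any other base is unchanged by the chemistry.
#'
#' @param allele single base on the plus strand.
#' @param strand read strand; on `"-"` the allele is complemented before the
#'   conversion calculus.
#' @return character vector of observable letters.
#' @export
observable_letters <- function(allele, strand = c("+", "-")) {
  strand <- match.arg(strand)
  stopifnot(allele %in% .BASES)
  a <- if (strand == "-") unname(.COMPLEMENT[allele]) else allele
  if (a == "C") c("C", "T") else a
}

#' Decide whether an SNP remains discriminative after bisulfite conversion
#'
#' A SNP is conversion-safe on a strand when the observable letter sets of its
#' two alleles are disjoint there.  Because conversion collapses C into {C, T},
#' any allele pair involving C vs T is confounded on that strand, while e.g.
#' G vs T or C vs A remain fully discriminative.
#'
#' @param ref_allele,alt_allele single plus-strand bases, different.
#' @param strand read strand.
#' @return list with `ref`, `alt`, `strand`, `safe` (logical), and the two
#'   observable letter sets `ref_set`, `alt_set`.
#' @export
conversion_safe <- function(ref_allele, alt_allele, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (identical(ref_allele, alt_allele)) stop("alleles must differ")
  rs <- observable_letters(ref_allele, strand)
  as <- observable_letters(alt_allele, strand)
  list(ref = ref_allele, alt = alt_allele, strand = strand,
       safe = length(intersect(rs, as)) == 0L, ref_set = rs, alt_set = as)
}

#' Conversion safety of a (possibly multiallelic) SNP
#'
#' A SNP is safe on a strand only when every allele pair is pairwise safe
#' there; otherwise variant calling ignores it on that strand.
#'
#' @param alleles character vector of plus-strand alleles (>= 2, unique).
#' @param strand read strand.
#' @return logical scalar.
#' @export
snp_safe <- function(alleles, strand = c("+", "-")) {
  strand <- match.arg(strand)
  alleles <- unique(alleles)
  stopifnot(length(alleles) >= 2L)
  prs <- utils::combn(alleles, 2L, simplify = FALSE)
  all(vapply(prs, function(p) conversion_safe(p[1], p[2], strand)$safe, logical(1)))
}
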