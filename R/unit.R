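#' Synthetic 35S rDNA unit architecture
#'
#' A 35S rDNA unit is modelled as an ordered tiling of elements: the rRNA genes
#' (18S, 5.8S, 26S) with their internal spacers (ITS1, ITS2), the external
#' transcribed spacers ETS1/ETS2, and an intergenic spacer built from seven
#' ~80 bp promoter elements P1-P7 (each carrying one copy of the PolI
#' TIS-like motif `TATATATRGGG`), five blocks of equally oriented 103 bp
#' R103 repeats, an `(AT)n` microsatellite (R2), the G4-prone `(CCTTGGG)7`
#' microsatellite (R7), and the R156 satellite of four partially degenerated
#' ~156 bp units.  The two prominent variants L and S differ in the copy
#' numbers of the R103b and R103d arrays and at diagnostic SNPs inside ETS2;
#' L-subvariants La/Ls differ at a G>A SNP that destroys an NlaIII site in La,
#' and an L-specific allele completes one of two MboI sites.
#'
#' Coordinates are 0-based half-open; the plus strand is the G-rich strand of
#' ETS2.
#'
#' @name rdna-unit
NULL

.mix_seed <- function(seed, k) {
  v <- (as.double(seed) %% 2147483647) * 69621 + as.double(k) * 7919 + 1013904223
  as.integer(v %% 2147483629) + 1L
}

.name_key <- function(name) sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)

# run expr under a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.seeded_bases <- function(n, seed) {
  .with_seed(seed, paste(sample(.BASES, n, replace = TRUE), collapse = ""))
}

#' Default structural blueprint of a 35S rDNA unit
#'
#' @param ets2_len length of ETS2 in bp (default 720: six 120 nt analysis
#'   regions I-VI).
#' @return object of class `rdna_unit_spec`: element table, diagnostic SNP
#'   table with the full allele universe, region and amplicon windows, and
#'   recipe parameters.
#' @export
rdna_unit_spec <- function(ets2_len = 720L) {
  stopifnot(ets2_len %% 120L == 0L, ets2_len >= 720L)
  elements <- data.frame(
    name = c("gene18S", "ITS1", "gene5.8S", "ITS2", "gene26S", "ETS1",
             "P1", "R103a", "P2", "R103b", "P3", "R2", "R7", "R156",
             "P4", "R103c", "P5", "R103d", "P6", "R103e", "P7", "ETS2"),
    recipe = c("filler", "filler", "filler", "filler", "filler", "filler",
               "promoter", "r103", "promoter", "r103", "promoter", "at_repeat",
               "r7", "r156", "promoter", "r103", "promoter", "r103",
               "promoter", "r103", "promoter", "ets2"),
    param = c(1800, 240, 160, 220, 2900, 380,
              80, 2, 80, NA, 80, 20, 7, 4, 80, 2, 80, NA, 80, 1, 80, ets2_len),
    stringsAsFactors = FALSE
  )
  # Diagnostic SNPs, ETS2 coordinates.  `alleles` is the allele universe used
  # to keep the shared backbone free of accidental restriction/motif sites for
  # every haplotype.  snp1/3/5/6 are triallelic (L ancestral A; S-major T; one
  # S-subvariant G each); snp2/4/7/8 separate all L from all S; `nla` is the
  # G>A transition inside the NlaIII target that isolates La.
  snps <- data.frame(
    snp_id  = c("snp1", "snp2", "snp3", "nla", "snp4", "snp7", "snp5", "snp6", "snp8"),
    pos     = c(75L, 95L, 155L, 215L, 280L, 337L, 450L, 560L, 660L),
    alleles = c("A,T,G", "G,T", "A,T,G", "G,A", "G,T", "G,T", "A,T,G", "A,T,G", "G,T"),
    stringsAsFactors = FALSE
  )
  # Fixed ETS2 bases completing the designed restriction targets:
  # CATG at 212..215 (NlaIII; 215 is the `nla` SNP), GATC at 337..340 (MboI;
  # 337 is `snp7`, G only in L), constitutive GATC at 637..640.
  designed <- data.frame(
    pos  = c(212L, 213L, 214L, 338L, 339L, 340L, 637L, 638L, 639L, 640L),
    base = c("C", "A", "T", "A", "T", "C", "G", "A", "T", "C"),
    stringsAsFactors = FALSE
  )
  nreg <- ets2_len %/% 120L
  regions <- data.frame(
    region = as.character(utils::as.roman(seq_len(nreg))),
    start = 120L * (seq_len(nreg) - 1L),
    end = 120L * seq_len(nreg),
    stringsAsFactors = FALSE
  )
  spec <- list(
    elements = elements,
    snps = snps,
    designed = designed,
    regions = regions,
    amplicons = list(mboi = c(60L, 665L), nlaiii = c(170L, 258L)),
    motif = "TATATATRGGG",
    promoter_motif_offset = 34L,
    r103_len = 103L,
    r156_len = 156L,
    r156_subs_per_copy = 4L,
    ets2_len = as.integer(ets2_len),
    coord = "0-based half-open; plus strand = G-rich ETS2 strand"
  )
  class(spec) <- "rdna_unit_spec"
  validate_unit_spec(spec)
  spec
}

#' Validate structural invariants of a unit blueprint
#'
#' @param spec an `rdna_unit_spec`.
#' @return the spec, invisibly; errors on violation.
#' @export
validate_unit_spec <- function(spec) {
  stopifnot(inherits(spec, "rdna_unit_spec"))
  el <- spec$elements
  fixed <- el$recipe %in% c("filler", "promoter", "at_repeat", "ets2")
  if (any(el$param[fixed] <= 0, na.rm = TRUE)) stop("element lengths must be positive")
  if (anyDuplicated(spec$snps$pos)) stop("SNP positions must be unique")
  if (any(spec$snps$pos < 0L | spec$snps$pos >= spec$ets2_len)) {
    stop("SNP positions must fall inside ETS2")
  }
  invisible(spec)
}

#' Default variant haplotypes for a lineage
#'
#' The por1-like lineage carries only S-subvariants (S1-S5; S1-S3 active with
#' S2 the most efficiently transcribed, S4/S5 silenced).  The por2-like
#' lineage carries both L and S variants with L more abundant; only La is
#' transcribed while Ls and all S-subvariants are silenced.
#'
#' @param lineage `"por1"` or `"por2"`.
#' @return data.frame: `variant_id`, `activity` (active/silent), `weight`
#'   (genome copy-number proportion, sums to 1), `multiplier`
#'   (specific-transcription multiplier, >= 0), R103b/R103d copy numbers, and
#'   one plus-strand allele column per diagnostic SNP.
#' @export
lineage_haplotypes <- function(lineage = c("por1", "por2")) {
  lineage <- match.arg(lineage)
  all_h <- data.frame(
    variant_id = c("La", "Ls", "S1", "S2", "S3", "S4", "S5"),
    r103b = c(7L, 7L, 3L, 3L, 3L, 3L, 3L),
    r103d = c(4L, 4L, 2L, 2L, 2L, 2L, 2L),
    snp1 = c("A", "A", "T", "G", "T", "T", "T"),
    snp2 = c("G", "G", "T", "T", "T", "T", "T"),
    snp3 = c("A", "A", "T", "T", "G", "T", "T"),
    nla  = c("A", "G", "G", "G", "G", "G", "G"),
    snp4 = c("G", "G", "T", "T", "T", "T", "T"),
    snp7 = c("G", "G", "T", "T", "T", "T", "T"),
    snp5 = c("A", "A", "T", "T", "T", "G", "T"),
    snp6 = c("A", "A", "T", "T", "T", "T", "G"),
    snp8 = c("G", "G", "T", "T", "T", "T", "T"),
    stringsAsFactors = FALSE
  )
  if (lineage == "por1") {
    h <- all_h[all_h$variant_id %in% c("S1", "S2", "S3", "S4", "S5"), ]
    h$activity <- c("active", "active", "active", "silent", "silent")
    h$weight <- c(0.40, 0.10, 0.20, 0.18, 0.12)
    h$multiplier <- c(1.0, 2.2, 1.3, 0, 0)
  } else {
    h <- all_h
    h$activity <- c("active", rep("silent", 6L))
    h$weight <- c(0.45, 0.10, 0.15, 0.08, 0.10, 0.07, 0.05)
    h$multiplier <- c(1, 0, 0, 0, 0, 0, 0)
  }
  rownames(h) <- NULL
  validate_haplotypes(h)
  h
}

#' Validate a haplotype table
#'
#' Checks the lineage-level invariants: genome weights sum to 1, all L differ
#' from all S at snp2/snp4/snp7/snp8, La is isolated by the NlaIII-site SNP,
#' and the allele vectors are pairwise distinct.
#'
#' @param haps haplotype data.frame as from [lineage_haplotypes()].
#' @return the table, invisibly.
#' @export
validate_haplotypes <- function(haps) {
  stopifnot(is.data.frame(haps), nrow(haps) >= 1L)
  if (abs(sum(haps$weight) - 1) > 1e-9) stop("genome weights must sum to 1")
  if (any(haps$multiplier < 0)) stop("specific-transcription multipliers must be >= 0")
  is_l <- startsWith(haps$variant_id, "L")
  for (s in c("snp2", "snp4", "snp7", "snp8")) {
    if (s %in% names(haps) && any(is_l) && any(!is_l) &&
        length(intersect(haps[[s]][is_l], haps[[s]][!is_l])) > 0L) {
      stop("alleles at ", s, " must separate all L from all S haplotypes")
    }
  }
  if (all(c("La", "Ls") %in% haps$variant_id)) {
    if (haps$nla[haps$variant_id == "La"] == haps$nla[haps$variant_id == "Ls"]) {
      stop("the NlaIII-site SNP must separate La from Ls")
    }
  }
  acols <- intersect(names(haps), c("snp1", "snp2", "snp3", "nla", "snp4",
                                    "snp7", "snp5", "snp6", "snp8"))
  pat <- apply(haps[, acols, drop = FALSE], 1L, paste, collapse = "")
  if (anyDuplicated(pat)) stop("haplotype allele vectors must be pairwise distinct")
  invisible(haps)
}

.snp_universe <- function(spec) {
  setNames(strsplit(spec$snps$alleles, ",", fixed = TRUE), spec$snps$snp_id)
}

# Deterministically mutate `chars` (a character vector of bases) so that no
# window can realize any of `patterns` (concrete base strings) under the
# per-position possibility sets implied by SNP allele universes and designed
# fixed bases.  `immutable` marks positions that must not be touched.
.scrub_patterns <- function(chars, patterns, possible, immutable, allowed_windows) {
  n <- length(chars)
  concrete <- all(lengths(possible) == 1L)
  find_hits <- function(pat) {
    k <- nchar(pat)
    if (n < k) return(integer(0))
    if (concrete) {
      s <- paste(chars, collapse = "")
      h <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
      if (h[1] == -1L) integer(0) else as.integer(h)
    } else {
      pc <- strsplit(pat, "", fixed = TRUE)[[1]]
      ok <- vapply(seq_len(n - k + 1L), function(s) {
        all(vapply(seq_len(k), function(j) pc[j] %in% possible[[s + j - 1L]],
                   logical(1)))
      }, logical(1))
      which(ok)
    }
  }
  for (iter in seq_len(60L)) {
    hit <- FALSE
    for (pat in patterns) {
      pc <- strsplit(pat, "", fixed = TRUE)[[1]]
      k <- length(pc)
      for (s in find_hits(pat)) {
        win <- s:(s + k - 1L)
        if (any(vapply(allowed_windows, function(w) s - 1L >= w[1] && s - 1L + k <= w[2],
                       logical(1)))) next
        if (!all(vapply(seq_len(k), function(j) pc[j] %in% possible[[win[j]]],
                        logical(1)))) next  # already broken this pass
        mut <- win[!immutable[win]]
        if (length(mut) == 0L) stop("cannot scrub pattern ", pat, ": window immutable")
        i <- mut[ceiling(length(mut) / 2)]
        j <- i - s + 1L
        repl <- setdiff(c("A", "T", "G", "C"), c(chars[i], pc[j]))[1]
        chars[i] <- repl
        possible[[i]] <- repl
        hit <- TRUE
      }
    }
    if (!hit) return(chars)
  }
  stop("pattern scrub did not converge")
}

# scrub a tandem-repeat monomer treating it as circular, so patterns cannot
# arise across head-to-tail junctions of exact copies
.scrub_circular <- function(mono, patterns) {
  ch <- strsplit(mono, "", fixed = TRUE)[[1]]
  n <- length(ch)
  for (iter in seq_len(60L)) {
    doubled <- paste(c(ch, ch), collapse = "")
    hit <- FALSE
    for (pat in patterns) {
      k <- nchar(pat)
      h <- gregexpr(paste0("(?=", pat, ")"), doubled, perl = TRUE)[[1]]
      h <- h[h != -1L & h <= n]
      if (length(h) == 0L) next
      s <- h[1]
      pc <- strsplit(pat, "", fixed = TRUE)[[1]]
      j <- k %/% 2L
      i <- ((s + j - 1L - 1L) %% n) + 1L
      ch[i] <- setdiff(c("A", "T", "G", "C"), c(ch[i], pc[j]))[1]
      hit <- TRUE
      break
    }
    if (!hit) return(paste(ch, collapse = ""))
  }
  stop("circular scrub did not converge")
}

.motif_patterns <- function(motif) {
  # expand IUPAC R and include the reverse complement so a plus-strand scan of
  # the reverse-complemented unit also finds nothing outside promoters
  fw <- c(sub("R", "A", motif, fixed = TRUE), sub("R", "G", motif, fixed = TRUE))
  c(fw, vapply(fw, revcomp, character(1)))
}

.build_r103_monomer <- function(spec, seed) {
  mono <- .seeded_bases(spec$r103_len, .mix_seed(seed, .name_key("R103mono")))
  .scrub_circular(mono, c("GATC", .motif_patterns(spec$motif)))
}

.build_promoter <- function(spec, name, seed) {
  off <- spec$promoter_motif_offset
  len <- spec$elements$param[spec$elements$name == name]
  r_base <- if (.name_key(name) %% 2L == 0L) "A" else "G"
  motif <- sub("R", r_base, spec$motif, fixed = TRUE)
  left <- .seeded_bases(off, .mix_seed(seed, .name_key(name) + 1L))
  right <- .seeded_bases(len - off - nchar(motif), .mix_seed(seed, .name_key(name) + 2L))
  seqc <- paste0(left, motif, right)
  ch <- strsplit(seqc, "", fixed = TRUE)[[1]]
  poss <- as.list(ch)
  # exactly one motif occurrence; no MboI target inside promoter elements.
  # The designed motif slot itself is immutable so scrubbing a partially
  # overlapping accidental hit can only touch the flanks.
  immutable <- rep(FALSE, length(ch))
  immutable[(off + 1L):(off + nchar(motif))] <- TRUE
  ch <- .scrub_patterns(ch, c("GATC", .motif_patterns(spec$motif)), poss,
                        immutable, list(c(off, off + nchar(motif))))
  paste(ch, collapse = "")
}

.build_r156 <- function(spec, seed) {
  mono <- .seeded_bases(spec$r156_len, .mix_seed(seed, .name_key("R156mono")))
  mono <- .scrub_circular(mono, .motif_patterns(spec$motif))
  ch0 <- strsplit(mono, "", fixed = TRUE)[[1]]
  pats <- .motif_patterns(spec$motif)
  for (salt in 0:19) {  # degenerate copies must not recreate a TIS motif
    copies <- character(4L)
    copies[1] <- mono
    for (k in 2:4) {
      ch <- .with_seed(.mix_seed(seed, .name_key("R156mono") + 31L * salt + k), {
        ch <- ch0
        idx <- sample(seq_along(ch), spec$r156_subs_per_copy)
        for (i in idx) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
        ch
      })
      copies[k] <- paste(ch, collapse = "")
    }
    out <- paste(copies, collapse = "")
    if (!any(vapply(pats, function(p) grepl(p, out, fixed = TRUE), logical(1)))) {
      return(out)
    }
  }
  stop("could not generate motif-free R156 satellite")
}

#' Build the ETS2 sequence of one haplotype
#'
#' The backbone (shared by all haplotypes under the same spec and seed) is
#' seeded uniform 50% GC filler with the designed NlaIII/MboI target bases
#' inserted, then scrubbed so that no GATC, CATG or TIS-motif occurrence can
#' arise outside the designed windows for any allele combination.  The
#' haplotype's alleles are substituted at the diagnostic SNP positions.
#'
#' @param spec an `rdna_unit_spec`.
#' @param haplotype one row of a haplotype table.
#' @param seed integer seed.
#' @return character scalar (plus strand, G-rich).
#' @export
build_ets2 <- function(spec, haplotype, seed) {
  stopifnot(nrow(haplotype) == 1L)
  n <- spec$ets2_len
  ch <- strsplit(.seeded_bases(n, .mix_seed(seed, .name_key("ETS2"))), "",
                 fixed = TRUE)[[1]]
  ch[spec$designed$pos + 1L] <- spec$designed$base
  uni <- .snp_universe(spec)
  poss <- as.list(ch)
  for (i in seq_len(nrow(spec$snps))) {
    poss[[spec$snps$pos[i] + 1L]] <- uni[[spec$snps$snp_id[i]]]
  }
  immutable <- rep(FALSE, n)
  immutable[spec$designed$pos + 1L] <- TRUE
  immutable[spec$snps$pos + 1L] <- TRUE
  allowed <- list(c(212L, 216L), c(337L, 341L), c(637L, 641L))  # designed targets
  ch <- .scrub_patterns(ch, c("GATC", "CATG", .motif_patterns(spec$motif)),
                        poss, immutable, allowed)
  for (i in seq_len(nrow(spec$snps))) {
    al <- haplotype[[spec$snps$snp_id[i]]]
    if (is.null(al) || is.na(al)) stop("haplotype lacks an allele for ", spec$snps$snp_id[i])
    ch[spec$snps$pos[i] + 1L] <- al
  }
  paste(ch, collapse = "")
}

.element_copies <- function(spec, haplotype, name) {
  el <- spec$elements
  p <- el$param[el$name == name]
  if (!is.na(p)) return(as.integer(p))
  switch(name,
         R103b = haplotype$r103b,
         R103d = haplotype$r103d,
         stop("no copy number for element ", name))
}

#' Build a full rDNA reference unit for one haplotype
#'
#' All element fillers are generated from per-element seeds derived from
#' `seed`, so two haplotypes built under the same spec and seed share an
#' identical backbone and differ exactly at the diagnostic SNP positions and
#' in the R103b/R103d array lengths.
#'
#' @param spec an `rdna_unit_spec`.
#' @param haplotype one row of a haplotype table (or a full table plus
#'   `variant_id` to select the row).
#' @param seed integer seed.
#' @param variant_id optional variant to select when `haplotype` has >1 row.
#' @return list with `sequence` (plus strand), `elements` (BED-style
#'   data.frame: name, start, end), `ets2_start`, `variant_id`.
#' @export
build_reference_unit <- function(spec, haplotype, seed, variant_id = NULL) {
  validate_unit_spec(spec)
  if (nrow(haplotype) > 1L) {
    if (is.null(variant_id)) stop("haplotype table has several rows; give variant_id")
    haplotype <- haplotype[haplotype$variant_id == variant_id, , drop = FALSE]
    if (nrow(haplotype) != 1L) stop("unknown variant_id: ", variant_id)
  }
  el <- spec$elements
  mono103 <- .build_r103_monomer(spec, seed)
  seqs <- character(nrow(el))
  for (i in seq_len(nrow(el))) {
    nm <- el$name[i]
    seqs[i] <- switch(el$recipe[i],
      filler = {
        s <- .seeded_bases(el$param[i], .mix_seed(seed, .name_key(nm)))
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        paste(.scrub_patterns(ch, .motif_patterns(spec$motif), as.list(ch),
                              rep(FALSE, length(ch)), list()), collapse = "")
      },
      promoter = .build_promoter(spec, nm, seed),
      r103 = strrep(mono103, .element_copies(spec, haplotype, nm)),
      at_repeat = strrep("AT", el$param[i]),
      r7 = strrep("CCTTGGG", el$param[i]),
      r156 = .build_r156(spec, seed),
      ets2 = build_ets2(spec, haplotype, seed),
      stop("unknown recipe ", el$recipe[i]))
  }
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens
  ann <- data.frame(name = el$name, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  full <- paste(seqs, collapse = "")
  # junction scrub: break TIS motifs straddling element boundaries, mutating
  # outside the (already clean) ETS2 and promoter motif slots
  ch <- strsplit(full, "", fixed = TRUE)[[1]]
  immutable <- rep(FALSE, length(ch))
  ets2_start <- starts[el$name == "ETS2"]
  immutable[(ets2_start + 1L):length(ch)] <- TRUE
  # keep exact tandem arrays intact: junction fixes go into neighbours instead
  for (i in which(el$recipe %in% c("r103", "r7", "at_repeat", "r156"))) {
    immutable[(starts[i] + 1L):ends[i]] <- TRUE
  }
  moff <- spec$promoter_motif_offset
  allowed <- lapply(which(el$recipe == "promoter"), function(i) {
    c(starts[i] + moff, starts[i] + moff + nchar(spec$motif))
  })
  for (w in allowed) immutable[(w[1] + 1L):w[2]] <- TRUE
  ch <- .scrub_patterns(ch, .motif_patterns(spec$motif), as.list(ch),
                        immutable, allowed)
  list(sequence = paste(ch, collapse = ""), elements = ann,
       ets2_start = ets2_start, variant_id = haplotype$variant_id)
}

#' Canonical reference haplotype of a unit blueprint
#'
#' Carries the first allele of each SNP's universe.  The canonical ETS2
#' backbone defines the site classification and positional rate lattice used
#' by every simulation and profile, independent of which lineage is being
#' analysed.
#'
#' @param spec an `rdna_unit_spec`.
#' @return one-row haplotype data.frame (`variant_id = "canonical"`).
#' @export
canonical_haplotype <- function(spec) {
  uni <- .snp_universe(spec)
  h <- data.frame(variant_id = "canonical", r103b = 7L, r103d = 4L,
                  stringsAsFactors = FALSE)
  for (s in names(uni)) h[[s]] <- uni[[s]][1]
  h
}

#' Build per-region and amplicon reference windows for read assignment
#'
#' The consensus window sequence uses the first haplotype's backbone (all
#' haplotypes share it outside SNP positions); SNP positions inside each
#' window are reported with every haplotype's allele so the identity filter
#' can exempt them.
#'
#' @param spec an `rdna_unit_spec`.
#' @param haplotypes haplotype table.
#' @param seed integer seed (must match the seed used to simulate reads).
#' @param windows which windows to build: the six 120 nt regions and/or the
#'   CAPS amplicons.
#' @return list of references; each has `name`, `start`, `end` (ETS2
#'   coordinates), `seq`, and `snps` (data.frame: snp_id, relpos, plus one
#'   allele column per variant).
#' @export
region_references <- function(spec, haplotypes, seed,
                              windows = c("regions", "mboi", "nlaiii")) {
  cons <- build_ets2(spec, canonical_haplotype(spec), seed)
  win <- list()
  if ("regions" %in% windows) {
    for (i in seq_len(nrow(spec$regions))) {
      win[[spec$regions$region[i]]] <- c(spec$regions$start[i], spec$regions$end[i])
    }
  }
  if ("mboi" %in% windows) win[["mboi_amplicon"]] <- spec$amplicons$mboi
  if ("nlaiii" %in% windows) win[["nlaiii_amplicon"]] <- spec$amplicons$nlaiii
  lapply(setNames(names(win), names(win)), function(nm) {
    w <- win[[nm]]
    inw <- spec$snps$pos >= w[1] & spec$snps$pos < w[2]
    sn <- spec$snps[inw, c("snp_id", "pos"), drop = FALSE]
    sn$relpos <- sn$pos - w[1]
    for (v in haplotypes$variant_id) {
      sn[[v]] <- vapply(sn$snp_id, function(s) {
        haplotypes[[s]][haplotypes$variant_id == v]
      }, character(1))
    }
    list(name = nm, start = w[1], end = w[2],
         seq = substr(cons, w[1] + 1L, w[2]), snps = sn)
  })
}

#' Extract a variant's amplicon sequence from its ETS2
#'
#' @param spec an `rdna_unit_spec`.
#' @param haplotype one-row haplotype table.
#' @param seed integer seed.
#' @param which `"mboi"` (605 bp) or `"nlaiii"` (88 bp).
#' @return character scalar.
#' @export
amplicon_sequence <- function(spec, haplotype, seed, which = c("mboi", "nlaiii")) {
  which <- match.arg(which)
  w <- spec$amplicons[[which]]
  ets2 <- build_ets2(spec, haplotype, seed)
  substr(ets2, w[1] + 1L, w[2])
}
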