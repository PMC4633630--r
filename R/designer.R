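# Hairpin designer: target-window enumeration, saiRNA / shRNA construction
# rules, duplex-end asymmetry scoring and cloning-oligo generation.
#
# Construction geometry (5'-arm designs): the guide strand starts with a fixed
# 5' adenine (position 1 need not pair the target), and positions 2 through
# stem+loop are complementary to the target window, read back from the window's
# 3' end; the loop itself base-pairs the target. The 3' arm is the reverse
# complement of the 5' arm except at the position opposite guide position 1,
# which is engineered as a C (or A) mismatch to bias guide-strand selection.

#' Design constraints for target-site scanning
#'
#' @param stem_len Stem length in bp, 14-24. The engineered terminal mismatch
#'   counts toward stem length.
#' @param loop_len Loop length in nt, 2-9 (canonical saiRNA loop is 4).
#' @param guide_arm `"FIVE"` (saiRNA and 5'-arm shRNA) or `"THREE"` (classic
#'   shRNA).
#' @param mismatch_base Residue placed opposite guide position 1, `"C"` or
#'   `"A"`.
#' @param gc_min,gc_max Acceptable GC fraction of the target window.
#' @param max_u_run Reject windows whose guide would contain this many or more
#'   consecutive U (pol III terminates prematurely on U runs; default 4).
#' @param loop_complementary Whether the loop pairs the target (TRUE for
#'   saiRNA-style designs).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(stem_len = 17L, loop_len = 4L,
                               guide_arm = c("FIVE", "THREE"),
                               mismatch_base = c("C", "A"),
                               gc_min = 0.25, gc_max = 0.75,
                               max_u_run = 4L, loop_complementary = TRUE) {
  guide_arm <- match.arg(guide_arm)
  mismatch_base <- match.arg(mismatch_base)
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  if (stem_len < 14L || stem_len > 24L) stop("stem_len must be in [14, 24]")
  if (loop_len < 2L || loop_len > 9L) stop("loop_len must be in [2, 9]")
  if (gc_min > gc_max) stop("gc_min must be <= gc_max")
  structure(list(stem_len = stem_len, loop_len = loop_len,
                 guide_arm = guide_arm, mismatch_base = mismatch_base,
                 gc_min = gc_min, gc_max = gc_max, max_u_run = max_u_run,
                 loop_complementary = loop_complementary),
            class = "design_constraints")
}

#' Enumerate candidate target sites on an mRNA
#'
#' Slides a window of `stem_len + loop_len` nt along the transcript (the
#' canonical 17+4 design consumes a 21-nt target) and applies the GC and
#' guide-homopolymer filters. Windows are reported in the RNA alphabet
#' together with up to 10 nt of downstream context, used by long-stem designs
#' whose guide extends past the window.
#'
#' @param mrna A single-row data.frame (or list) with fields `id` and `seq`,
#'   e.g. one row of [read_fasta()] output.
#' @param constraints A [design_constraints()] object.
#' @param apply_filters Set `FALSE` to enumerate every position.
#' @return A data.frame of class `target_sites`: `source_id`, `start`
#'   (1-based), `window`, `gc`, `context3`.
#' @export
scan_target_sites <- function(mrna, constraints = design_constraints(),
                              apply_filters = TRUE) {
  seq <- dna_to_rna(validate_nucseq(mrna$seq))
  wlen <- constraints$stem_len + constraints$loop_len
  n <- nchar(seq)
  empty <- data.frame(source_id = character(), start = integer(),
                      window = character(), gc = numeric(),
                      context3 = character(), stringsAsFactors = FALSE)
  if (n < wlen) {
    warning("mRNA '", mrna$id, "' shorter than the ", wlen, "-nt design window")
    return(structure(empty, class = c("target_sites", "data.frame")))
  }
  starts <- seq_len(n - wlen + 1L)
  windows <- substring(seq, starts, starts + wlen - 1L)
  gc <- vapply(windows, gc_content, numeric(1), USE.NAMES = FALSE)
  ctx <- substring(seq, starts + wlen, pmin(n, starts + wlen + 9L))
  keep <- rep(TRUE, length(starts))
  if (apply_filters) {
    keep <- gc >= constraints$gc_min & gc <= constraints$gc_max
    guides <- vapply(windows, function(w) build_guide_seq(w), character(1),
                     USE.NAMES = FALSE)
    keep <- keep & vapply(guides, function(g) max_run(g, "U"),
                          integer(1), USE.NAMES = FALSE) < constraints$max_u_run
  }
  out <- data.frame(source_id = rep(mrna$id, sum(keep)), start = starts[keep],
                    window = windows[keep], gc = gc[keep],
                    context3 = ctx[keep], stringsAsFactors = FALSE)
  structure(out[order(out$start), , drop = FALSE],
            class = c("target_sites", "data.frame"))
}

# Core guide rule: fixed 5' A, then the reverse complement of all but the
# window's last residue (guide position 1 sits opposite that residue).
build_guide_seq <- function(window) {
  n <- nchar(window)
  paste0("A", revcomp(substr(window, 1L, n - 1L), "RNA"))
}

#' Build the guide strand for a target window
#'
#' Guide position 1 is fixed as A (5' A/U has the highest Ago affinity and
#' pairing of position 1 with the target is dispensable); positions 2..n are
#' the reverse complement of window positions 1..n-1.
#'
#' @param site One row of [scan_target_sites()] output, or a list with a
#'   `window` field.
#' @return A list of class `guide_strand`: `seq`, `pos1_forced`,
#'   `pos1_mismatch` (TRUE unless the window ends in U), `complementary_span`.
#' @export
build_guide <- function(site) {
  window <- dna_to_rna(validate_nucseq(site$window))
  n <- nchar(window)
  if (n < 8L) stop("target window too short to design a guide")
  seq <- build_guide_seq(window)
  structure(list(seq = seq, pos1_forced = TRUE,
                 pos1_mismatch = substr(window, n, n) != "U",
                 complementary_span = c(2L, n)),
            class = "guide_strand")
}

new_hairpin_design <- function(arm5, loop, arm3, guide, guide_arm, mismatches,
                               stem_len, loop_len, site,
                               loop_complementary) {
  structure(list(arm5 = arm5, loop = loop, arm3 = arm3, guide = guide,
                 guide_arm = guide_arm, mismatches = as.integer(mismatches),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 site = site, loop_complementary = loop_complementary),
            class = "hairpin_design")
}

#' Full hairpin (precursor core) sequence of a design
#' @param design A `hairpin_design`.
#' @return RNA character scalar `arm5 + loop + arm3`
#'   (`2 * stem_len + loop_len` nt).
#' @export
hairpin_seq <- function(design) paste0(design$arm5, design$loop, design$arm3)

#' @export
print.hairpin_design <- function(x, ...) {
  kind <- if (x$guide_arm == "FIVE" && x$stem_len >= 16 && x$stem_len <= 18)
    "saiRNA" else if (x$guide_arm == "THREE") "classic shRNA" else "shRNA (5'-arm guide)"
  cat(sprintf("%s design: %d-bp stem, %d-nt loop (%d-nt core)\n",
              kind, x$stem_len, x$loop_len, 2L * x$stem_len + x$loop_len))
  cat(sprintf("  5' arm: %s\n  loop  : %s\n  3' arm: %s\n", x$arm5, x$loop, x$arm3))
  cat(sprintf("  guide (%s' arm): %s\n", if (x$guide_arm == "FIVE") "5" else "3",
              x$guide))
  if (length(x$mismatches)) {
    cat("  engineered mismatch at stem position(s):",
        paste(x$mismatches, collapse = ", "), "\n")
  }
  invisible(x)
}

#' General 5'-arm-guide hairpin constructor (stems 14-24 bp)
#'
#' Assembles a hairpin by the 5'-arm rules — fixed 5' A, target
#' complementarity from guide position 2 through the loop, terminal
#' mismatch opposite guide position 1 — for any stem length in the studied
#' 14-24 bp range, including the 19-20 bp dead zone. [build_sairna()] and
#' [build_shrna_5arm()] are range-checked wrappers for the two functional
#' categories.
#'
#' @inheritParams build_guide
#' @param stem_len Stem length in bp, 14-24.
#' @param loop_len Loop length in nt, 2-9.
#' @param mismatch_base Residue opposite guide position 1, `"C"` or `"A"`.
#' @return A `hairpin_design` with `guide_arm = "FIVE"`.
#' @export
build_hairpin_5arm <- function(site, stem_len, loop_len = 4L,
                               mismatch_base = c("C", "A")) {
  mismatch_base <- match.arg(mismatch_base)
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  if (stem_len < 14L || stem_len > 24L) stop("stem_len must be in [14, 24]")
  if (loop_len < 2L || loop_len > 9L) stop("loop_len must be in [2, 9]")
  build_5arm_hairpin(site, stem_len, loop_len, mismatch_base)
}

# Shared 5'-arm-guide hairpin assembly (saiRNA and long-stem shRNA).
build_5arm_hairpin <- function(site, stem_len, loop_len, mismatch_base) {
  window <- dna_to_rna(validate_nucseq(site$window))
  m <- nchar(window)
  core_len <- stem_len + loop_len
  if (core_len <= m) {
    if (core_len != m) {
      stop("window length (", m, ") must equal stem_len + loop_len (", core_len, ")")
    }
    guide <- build_guide(site)$seq
  } else {
    # Guide longer than the window: complementarity is capped at the window
    # (positions 2..m); the remainder is copied from the mRNA context
    # immediately downstream of the window.
    ctx <- if (!is.null(site$context3)) dna_to_rna(site$context3) else ""
    need <- core_len - m
    if (nchar(ctx) < need) {
      stop("insufficient downstream mRNA context (need ", need, " nt) for a ",
           stem_len, "-bp stem on a ", m, "-nt window")
    }
    guide <- paste0(build_guide_seq(window), substr(ctx, 1L, need))
  }
  arm5 <- substr(guide, 1L, stem_len)
  loop <- substr(guide, stem_len + 1L, core_len)
  arm3 <- revcomp(arm5, "RNA")
  substr(arm3, stem_len, stem_len) <- mismatch_base
  new_hairpin_design(arm5, loop, arm3, guide, "FIVE", mismatches = 1L,
                     stem_len, loop_len, site, loop_complementary = TRUE)
}

#' Build a saiRNA hairpin (16-18 bp stem, Ago2-processed)
#'
#' The guide occupies the 5' arm and runs into a target-complementary loop;
#' the 3' arm is its reverse complement with the residue opposite guide
#' position 1 replaced by `mismatch_base`. The mismatched terminal position
#' counts toward stem length.
#'
#' @inheritParams build_guide
#' @param stem_len Stem length in bp, 16-18.
#' @param loop_len Loop length in nt (default 4).
#' @param mismatch_base `"C"` (default) or `"A"`.
#' @return A `hairpin_design` with `guide_arm = "FIVE"`.
#' @examples
#' site <- list(window = "AACUUCAGGGUCAGCUUGCCG")
#' d <- build_sairna(site)            # 17 + 4 canonical design, 38-nt core
#' hairpin_seq(d)
#' @export
build_sairna <- function(site, stem_len = 17L, loop_len = 4L,
                         mismatch_base = c("C", "A")) {
  mismatch_base <- match.arg(mismatch_base)
  stem_len <- as.integer(stem_len)
  if (stem_len < 16L || stem_len > 18L) {
    stop("saiRNA stems are 16-18 bp; use build_shrna_5arm / build_shrna_classic ",
         "for longer stems")
  }
  build_5arm_hairpin(site, stem_len, as.integer(loop_len), mismatch_base)
}

#' Build a Dicer-substrate shRNA with the guide in the 5' arm
#'
#' Same construction rules as [build_sairna()] but with a 21-24 bp stem.
#' Complementarity to the target is capped at the window; guide positions past
#' the window are copied from the mRNA context downstream of it.
#'
#' @inheritParams build_sairna
#' @param stem_len Stem length in bp, 21-24.
#' @param loop_len Loop length in nt, 4 or 7.
#' @export
build_shrna_5arm <- function(site, stem_len = 22L, loop_len = 4L,
                             mismatch_base = c("C", "A")) {
  mismatch_base <- match.arg(mismatch_base)
  stem_len <- as.integer(stem_len)
  if (stem_len < 21L || stem_len > 24L) {
    stop("5'-arm shRNA stems are 21-24 bp; use build_sairna for 16-18 bp stems")
  }
  if (!as.integer(loop_len) %in% c(4L, 7L)) stop("loop_len must be 4 or 7")
  build_5arm_hairpin(site, stem_len, as.integer(loop_len), mismatch_base)
}

#' Build a classic pLKO.1-style shRNA (21-bp stem, guide in the 3' arm)
#'
#' The 5' arm is the sense (window-identical) sequence, the 3' arm the
#' antisense guide, joined by a fixed non-complementary loop. No 5' A is
#' forced and no mismatch is engineered.
#'
#' @inheritParams build_guide
#' @param stem_len Stem length in bp (default 21).
#' @param loop Loop sequence (default the 6-nt TRC/pLKO.1 loop `"CUCGAG"`).
#' @export
build_shrna_classic <- function(site, stem_len = 21L, loop = "CUCGAG") {
  stem_len <- as.integer(stem_len)
  window <- dna_to_rna(validate_nucseq(site$window))
  if (nchar(window) < stem_len) stop("window shorter than stem_len")
  loop <- dna_to_rna(validate_nucseq(loop))
  arm5 <- substr(window, 1L, stem_len)        # sense / passenger
  arm3 <- revcomp(arm5, "RNA")                # antisense guide
  new_hairpin_design(arm5, loop, arm3, guide = arm3, guide_arm = "THREE",
                     mismatches = integer(0), stem_len, nchar(loop), site,
                     loop_complementary = FALSE)
}

# RNA nearest-neighbour Watson-Crick stacking free energies at 37 C, kcal/mol
# (Xia et al. 1998, Biochemistry 37:14719, as used in the Turner 2004 rules).
# Keyed by the 5'->3' dinucleotide on one strand; the complementary strand is
# implied. The 16 keys collapse to the 10 published unique parameters by
# duplex symmetry.
RNA_NN_DG37 <- c(
  AA = -0.93, UU = -0.93,
  AU = -1.10, UA = -1.33,
  CU = -2.08, AG = -2.08,
  CA = -2.11, UG = -2.11,
  GU = -2.24, AC = -2.24,
  GA = -2.35, UC = -2.35,
  CG = -2.36,
  GG = -3.26, CC = -3.26,
  GC = -3.42
)

# dG of the three stacks in a 4-bp terminal window, reading the given strand
# 5'->3'. `paired` flags (length 4) mark positions that are Watson-Crick
# paired; stacks touching an unpaired (mismatched) position contribute zero.
dg_terminal4 <- function(strand4, paired = rep(TRUE, 4L)) {
  chars <- strsplit(strand4, "", fixed = TRUE)[[1]]
  if (length(chars) != 4L) stop("terminal window must be 4 nt")
  total <- 0
  for (i in 1:3) {
    if (paired[i] && paired[i + 1L]) {
      total <- total + RNA_NN_DG37[[paste0(chars[i], chars[i + 1L])]]
    }
  }
  total
}

#' Duplex-end asymmetry score
#'
#' Compares the thermodynamic stability of the terminal 4 bp at the guide
#' strand's 5' end against the terminal 4 bp at the passenger strand's 5' end,
#' using an embedded RNA nearest-neighbour free-energy table (37 C).
#' The score is `dG(passenger 5' window) - dG(guide 5' window)`: negative
#' values mean the guide 5' end is the less stably paired duplex end, which
#' favours guide-strand retention by RISC. Engineered mismatch positions
#' contribute zero stacking.
#'
#' @param design A `hairpin_design` with at least a 4-bp stem.
#' @return Signed free-energy difference in kcal/mol.
#' @export
asymmetry_score <- function(design) {
  s <- design$stem_len
  if (s < 4L) stop("stem must be at least 4 bp")
  paired_at <- function(stem_pos) !stem_pos %in% design$mismatches
  if (design$guide_arm == "FIVE") {
    guide_strand <- design$arm5; pass_strand <- design$arm3
  } else {
    guide_strand <- design$arm3; pass_strand <- design$arm5
  }
  # Strand position j corresponds to stem position j for the 5' arm and
  # stem position s+1-j for the 3' arm.
  strand_paired <- function(arm) {
    if (identical(arm, "FIVE")) vapply(1:4, paired_at, logical(1))
    else vapply(s + 1L - (1:4), paired_at, logical(1))
  }
  g_arm <- if (design$guide_arm == "FIVE") "FIVE" else "THREE"
  p_arm <- if (design$guide_arm == "FIVE") "THREE" else "FIVE"
  dg_guide <- dg_terminal4(substr(guide_strand, 1L, 4L), strand_paired(g_arm))
  dg_pass <- dg_terminal4(substr(pass_strand, 1L, 4L), strand_paired(p_arm))
  dg_pass - dg_guide
}

#' Rank candidate designs
#'
#' Combines per-design subscores into a weighted total (lower is better):
#' the asymmetry score, the window GC deviation from 0.5, the longest guide
#' homopolymer run, and optionally a precomputed off-target seed-site load.
#' The order is a stable total order; ties break toward the 5'-most target
#' position.
#'
#' @param designs A list of `hairpin_design` objects.
#' @param weights Named numeric weights for `asymmetry`, `gc`, `homopolymer`,
#'   `offtarget`.
#' @param offtarget_load Optional numeric vector (one value per design), e.g.
#'   total seed-site counts from [scan_seed_matches()].
#' @return A data.frame with one row per design, subscores, total and rank,
#'   ordered best-first; the designs themselves in attribute `"designs"`.
#' @export
rank_candidates <- function(designs,
                            weights = c(asymmetry = 1, gc = 1,
                                        homopolymer = 0.5, offtarget = 1),
                            offtarget_load = NULL) {
  if (length(designs) < 1L) stop("need at least one design")
  if (inherits(designs, "hairpin_design")) designs <- list(designs)
  asym <- vapply(designs, asymmetry_score, numeric(1))
  gc_dev <- vapply(designs, function(d) abs(gc_content(d$site$window) - 0.5),
                   numeric(1))
  homop <- vapply(designs, function(d) max_homopolymer(d$guide), numeric(1))
  ot <- if (is.null(offtarget_load)) rep(0, length(designs)) else offtarget_load
  start <- vapply(designs, function(d)
    if (!is.null(d$site$start)) as.integer(d$site$start) else NA_integer_,
    integer(1))
  total <- weights[["asymmetry"]] * asym + weights[["gc"]] * gc_dev +
    weights[["homopolymer"]] * homop + weights[["offtarget"]] * ot
  ord <- order(total, start, seq_along(designs))
  out <- data.frame(rank = seq_along(designs),
                    start = start[ord],
                    asymmetry = asym[ord], gc_dev = gc_dev[ord],
                    homopolymer = homop[ord], offtarget = ot[ord],
                    total = total[ord], stringsAsFactors = FALSE)
  attr(out, "designs") <- designs[ord]
  attr(out, "weights") <- weights
  out
}

# Cloning geometry per vector: upstream enzyme is always BamHI (5' GATC
# overhang); the downstream enzyme determines the other end. `top_suffix` /
# `bottom_prefix` are the downstream flank strings on each oligo; SphI leaves
# a 4-nt 3'-recessed (CATG) end rather than a 5' overhang.
CLONING_VECTORS <- list(
  H1_pSilencer    = list(enzymes = c("BamHI", "HindIII"),
                         top_prefix = "GATCC", top_suffix = "A",
                         bottom_prefix = "AGCTT", bottom_suffix = "G"),
  lenti_shRNA     = list(enzymes = c("BamHI", "XbaI"),
                         top_prefix = "GATCC", top_suffix = "T",
                         bottom_prefix = "CTAGA", bottom_suffix = "G"),
  lenti_saiRNA_RZ = list(enzymes = c("BamHI", "SphI"),
                         top_prefix = "GATCC", top_suffix = "GCATG",
                         bottom_prefix = "C", bottom_suffix = "G")
)

ENZYME_SITES <- c(BamHI = "GGATCC", HindIII = "AAGCTT", XbaI = "TCTAGA",
                  SphI = "GCATGC")

#' Generate annealing oligos for cloning a cassette
#'
#' Produces the top/bottom DNA oligo pair whose annealed duplex reconstructs
#' the insert (hairpin, plus spacer and ribozyme when the cassette carries
#' one, followed by the poly-T terminator) with the sticky ends of the named
#' vector's enzyme pair.
#'
#' @param cassette An `expression_cassette` (see [attach_ribozyme()]) or a
#'   bare `hairpin_design`.
#' @param vector One of `"H1_pSilencer"` (BamHI/HindIII), `"lenti_shRNA"`
#'   (BamHI/XbaI), `"lenti_saiRNA_RZ"` (BamHI/SphI).
#' @param terminator_len Number of terminator T's appended (default 6).
#' @return A list of class `oligo_pair`: `top`, `bottom` (DNA, 5'->3'),
#'   `vector`, `enzymes`, `insert`, `terminator_len`.
#' @export
make_cloning_oligos <- function(cassette,
                                vector = c("H1_pSilencer", "lenti_shRNA",
                                           "lenti_saiRNA_RZ"),
                                terminator_len = 6L) {
  vector <- match.arg(vector)
  spec <- CLONING_VECTORS[[vector]]
  insert_rna <- if (inherits(cassette, "expression_cassette")) {
    paste0(hairpin_seq(cassette$hairpin), cassette$spacer,
           if (!is.null(cassette$ribozyme)) cassette$ribozyme$seq else "")
  } else if (inherits(cassette, "hairpin_design")) {
    hairpin_seq(cassette)
  } else stop("cassette must be an expression_cassette or hairpin_design")
  if (inherits(cassette, "expression_cassette")) {
    terminator_len <- cassette$terminator_len
  }
  insert <- paste0(rna_to_dna(insert_rna), strrep("T", terminator_len))
  for (enz in spec$enzymes) {
    site <- ENZYME_SITES[[enz]]
    hits <- gregexpr(site, insert, fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      stop(enz, " site (", site, ") occurs inside the insert at position(s) ",
           paste(hits, collapse = ", "))
    }
  }
  top <- paste0(spec$top_prefix, insert, spec$top_suffix)
  bottom <- paste0(spec$bottom_prefix, revcomp(insert, "DNA"),
                   spec$bottom_suffix)
  structure(list(top = top, bottom = bottom, vector = vector,
                 enzymes = spec$enzymes, insert = insert,
                 terminator_len = as.integer(terminator_len)),
            class = "oligo_pair")
}
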