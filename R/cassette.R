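# Expression cassette model: HDV ribozyme fusion, pol III (H1/U6) and T7
# transcription, ribozyme self-cleavage with explicit end chemistry, and
# template-directed folding of the transcript back onto its design.

# Genomic HDV ribozyme, 85 nt, catalytic C at position 75. A standard
# published self-cleaving sequence; cleavage occurs immediately 5' of
# ribozyme nt 1 and requires no base pairing with upstream flanking sequence.
HDV_RIBOZYME_SEQ <- paste0(
  "GGCCGGCAUGGUCCCAGCCUCCUCGCUGGCGCCGGCUGGGCAACAUUCCGAGGGGACCGUCCCCUCGGUAAUGGCGAAUGGGACC"
)

#' HDV ribozyme specification
#'
#' @param seq Ribozyme sequence (RNA). Default: the 85-nt genomic HDV
#'   ribozyme. Fully overridable for engineered variants.
#' @param variant `"WT"` or `"C75U"`; the C75U point mutation at the catalytic
#'   site abolishes self-cleavage.
#' @param catalytic_pos Position of the catalytic C (default 75).
#' @param cleavage_offset Nucleotides upstream of ribozyme position 1 at which
#'   scission occurs (default 0 = immediately 5' of the ribozyme).
#' @return A list of class `ribozyme_spec` with an `active` flag.
#' @export
ribozyme_spec <- function(seq = HDV_RIBOZYME_SEQ, variant = c("WT", "C75U"),
                          catalytic_pos = 75L, cleavage_offset = 0L) {
  variant <- match.arg(variant)
  seq <- dna_to_rna(validate_nucseq(seq))
  catalytic_pos <- as.integer(catalytic_pos)
  if (catalytic_pos < 1L || catalytic_pos > nchar(seq)) {
    stop("catalytic_pos outside the ribozyme sequence")
  }
  if (substr(seq, catalytic_pos, catalytic_pos) != "C") {
    stop("catalytic position ", catalytic_pos, " is not a C")
  }
  if (variant == "C75U") substr(seq, catalytic_pos, catalytic_pos) <- "U"
  structure(list(seq = seq, variant = variant, catalytic_pos = catalytic_pos,
                 cleavage_offset = as.integer(cleavage_offset),
                 active = variant == "WT"),
            class = "ribozyme_spec")
}

#' Transcript with explicit end chemistry
#'
#' @param seq RNA sequence.
#' @param five_prime,three_prime End chemistry (see [end_chemistry()]).
#' @param weight Ensemble weight (probability).
#' @return A list of class `transcript`; `u_tail_len` is derived from the
#'   terminal U run.
#' @export
transcript <- function(seq, five_prime = "PPP", three_prime = "OH",
                       weight = 1) {
  seq <- dna_to_rna(validate_nucseq(seq))
  tail <- attr(regexpr("U*$", seq), "match.length")
  structure(list(seq = seq, ends = end_chemistry(five_prime, three_prime),
                 u_tail_len = as.integer(tail), weight = weight),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript: %d nt, 5'-%s / %s-3', weight %.3g\n",
              nchar(x$seq), x$ends$five_prime, x$ends$three_prime, x$weight))
  cat(" ", x$seq, "\n")
  invisible(x)
}

#' Fuse an HDV ribozyme downstream of a hairpin design
#'
#' Places the ribozyme 3' of the hairpin so that self-cleavage leaves exactly
#' `nchar(spacer)` nt beyond the 3' arm — the post-cleavage 3' overhang.
#'
#' @param design A `hairpin_design`.
#' @param variant `"WT"`, `"C75U"`, or `"none"` (no ribozyme).
#' @param spacer Sequence between the 3' arm and the ribozyme (default
#'   `"UU"`, giving the short 2-nt overhang that licenses Ago2 binding);
#'   0-5 nt.
#' @param promoter `"H1"`, `"U6"` or `"T7"`.
#' @param terminator_len Length of the poly-T terminator in the DNA template
#'   (pol III requires >= 5).
#' @param ribozyme Optional full [ribozyme_spec()] override.
#' @return A list of class `expression_cassette`.
#' @export
attach_ribozyme <- function(design, variant = c("WT", "C75U", "none"),
                            spacer = "UU", promoter = c("H1", "U6", "T7"),
                            terminator_len = 6L, ribozyme = NULL) {
  variant <- match.arg(variant)
  promoter <- match.arg(promoter)
  stopifnot(inherits(design, "hairpin_design"))
  if (variant == "none") spacer <- ""   # bare design + terminator only
  if (nchar(spacer) > 0L) {
    spacer <- dna_to_rna(validate_nucseq(spacer))
    if (max_run(spacer, "U") >= 4L) {
      stop("spacer contains a run of >= 4 U: pol III would terminate inside it")
    }
  }
  if (nchar(spacer) > 5L) stop("spacer must be 0-5 nt")
  rz <- if (variant == "none") NULL
        else if (!is.null(ribozyme)) ribozyme
        else ribozyme_spec(variant = variant)
  terminator_len <- as.integer(terminator_len)
  if (promoter %in% c("H1", "U6") && terminator_len < 5L) {
    stop("pol III cassettes need a terminator of >= 5 T")
  }
  structure(list(promoter = promoter, hairpin = design, spacer = spacer,
                 ribozyme = rz, terminator_len = terminator_len),
            class = "expression_cassette")
}

# RNA body templated by the cassette (hairpin [+ spacer + ribozyme]), no tail.
cassette_body <- function(cassette) {
  paste0(hairpin_seq(cassette$hairpin), cassette$spacer,
         if (!is.null(cassette$ribozyme)) cassette$ribozyme$seq else "")
}

#' Transcribe a cassette with RNA polymerase III
#'
#' Pol III terminates on the poly-T signal and leaves 4-6 templated uridines
#' on the transcript 3' end; the ensemble carries one species per tail length
#' with the given weights. All species start with a 5' triphosphate.
#'
#' @param cassette An `expression_cassette` with an H1 or U6 promoter.
#' @param tail_weights Named or positional weights for U-tail lengths 4, 5, 6
#'   (default uniform); normalized to sum to 1.
#' @return A list of class `transcript_ensemble` (list of `transcript`s whose
#'   weights sum to 1).
#' @export
transcribe_pol3 <- function(cassette, tail_weights = c(1, 1, 1) / 3) {
  stopifnot(inherits(cassette, "expression_cassette"))
  if (!cassette$promoter %in% c("H1", "U6")) {
    stop("transcribe_pol3 requires an H1 or U6 promoter (got ",
         cassette$promoter, ")")
  }
  if (cassette$terminator_len < 5L) stop("missing pol III terminator")
  body <- cassette_body(cassette)
  first <- substr(body, 1L, 1L)
  if (cassette$promoter == "H1" && first != "A") {
    stop("H1 transcription initiates on A; design the +1 residue as A")
  }
  if (cassette$promoter == "U6" && first != "G") {
    warning("U6 initiates most efficiently on G; +1 residue is ", first)
  }
  if (length(tail_weights) != 3L || any(tail_weights < 0)) {
    stop("tail_weights must be 3 non-negative values for tails 4, 5, 6 nt")
  }
  w <- tail_weights / sum(tail_weights)
  species <- mapply(function(len, wt) {
    transcript(paste0(body, strrep("U", len)), "PPP", "OH", wt)
  }, 4:6, w, SIMPLIFY = FALSE)
  structure(species, class = "transcript_ensemble")
}

#' Transcribe a cassette in vitro with T7 RNA polymerase
#'
#' A single full-length run-off transcript of the templated insert; no U-tail
#' model.
#'
#' @param cassette An `expression_cassette` with the T7 promoter.
#' @return A single `transcript` (weight 1, 5' PPP).
#' @export
transcribe_t7 <- function(cassette) {
  stopifnot(inherits(cassette, "expression_cassette"))
  if (cassette$promoter != "T7") stop("transcribe_t7 requires the T7 promoter")
  transcript(cassette_body(cassette), "PPP", "OH", 1)
}

#' Reconstruct a T7 hairpin-ribozyme fusion transcript from cloning oligos
#'
#' Reads a FASTA of template oligos (e.g. a published supplementary oligo
#' table), anneals/concatenates the top-strand insert they encode, and returns
#' the single T7 fusion transcript. With an inactive (C75U) ribozyme the
#' fusion stays intact, so its length is the full insert length.
#'
#' @param oligo_fasta Path to a FASTA of DNA template oligos for one
#'   construct, in order, top strand.
#' @return A `transcript`, or `NA` (with a warning) when `oligo_fasta` is
#'   missing or does not exist.
#' @export
reconstruct_t7_fusion <- function(oligo_fasta) {
  if (is.null(oligo_fasta) || !file.exists(oligo_fasta %||% "")) {
    warning("construct oligo FASTA not provided; cannot reconstruct the T7 fusion")
    return(NA)
  }
  recs <- read_fasta(oligo_fasta, alphabet = "DNA")
  if (nrow(recs) == 0L) {
    warning("no oligo records in ", oligo_fasta)
    return(NA)
  }
  transcript(dna_to_rna(paste(recs$seq, collapse = "")), "PPP", "OH", 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ribozyme self-cleavage of a transcript
#'
#' Locates the ribozyme in the transcript (it must be present as a contiguous
#' block, anchored at the 3' end up to a terminal U-tail) and, when the
#' ribozyme is active, cleaves immediately 5' of its first residue (shifted
#' by `cleavage_offset`). The upstream product carries the diagnostic
#' 2',3'-cyclic phosphate; the downstream product starts with a 5' hydroxyl.
#' Inactive (C75U) ribozymes never cleave.
#'
#' @param t A `transcript`.
#' @param rz A `ribozyme_spec`.
#' @return A list of class `cleavage_result`: `occurred`, `upstream`,
#'   `downstream` (both `transcript`s; `NULL` downstream when no cleavage).
#' @export
ribozyme_cleave <- function(t, rz) {
  stopifnot(inherits(t, "transcript"), inherits(rz, "ribozyme_spec"))
  pos <- regexpr(rz$seq, t$seq, fixed = TRUE)[1]
  if (pos == -1L) stop("ribozyme sequence not found in the transcript")
  if (!rz$active) {
    return(structure(list(occurred = FALSE, upstream = t, downstream = NULL),
                     class = "cleavage_result"))
  }
  cut <- pos - 1L - rz$cleavage_offset   # last residue of the upstream product
  if (cut < 1L) stop("cleavage point falls before the transcript start")
  up <- transcript(substr(t$seq, 1L, cut), t$ends$five_prime, "CyclicP",
                   t$weight)
  down <- transcript(substr(t$seq, cut + 1L, nchar(t$seq)), "OH",
                     t$ends$three_prime, t$weight)
  structure(list(occurred = TRUE, upstream = up, downstream = down),
            class = "cleavage_result")
}

#' Convert a 2',3'-cyclic phosphate to a 3' hydroxyl (T4 PNK, no ATP)
#'
#' Sequence is unchanged; only the 3' end chemistry is converted. Idempotent:
#' an input that already carries a 3' OH is returned as-is with a warning.
#'
#' @param t A `transcript`.
#' @return The same `transcript` with `three_prime = "OH"`.
#' @export
pnk_dephosphorylate <- function(t) {
  stopifnot(inherits(t, "transcript"))
  if (t$ends$three_prime == "OH") {
    warning("transcript already carries a 3' OH; returned unchanged")
    return(t)
  }
  transcript(t$seq, t$ends$five_prime, "OH", t$weight)
}

#' Fold a transcript onto its hairpin design
#'
#' Template-directed pairing against the known design (not free-energy
#' folding): the stem pairs are the design's declared pairs, and the 5'/3'
#' overhangs are the unpaired terminal runs outside the arms — for a
#' ribozyme-cleaved transcript the 3' overhang is the spacer remnant, for an
#' uncleaved pol III transcript it is spacer plus U-tail (plus any ribozyme).
#'
#' @param t A `transcript` containing the design's arms.
#' @param design The `hairpin_design` the transcript was templated from.
#' @return A list of class `folded_precursor`: `stem_pairs` (two-column
#'   matrix of paired transcript positions), `loop_span`, `overhang5`,
#'   `overhang3`, `stem_len`, `source`, `design`.
#' @export
fold_hairpin <- function(t, design) {
  stopifnot(inherits(t, "transcript"), inherits(design, "hairpin_design"))
  core <- hairpin_seq(design)
  pos <- regexpr(core, t$seq, fixed = TRUE)[1]
  if (pos == -1L) stop("transcript does not contain the design's hairpin core")
  s <- design$stem_len; l <- design$loop_len
  off <- pos - 1L
  paired <- setdiff(seq_len(s), design$mismatches)
  stem_pairs <- cbind(i = off + paired,
                      j = off + 2L * s + l + 1L - paired)
  structure(list(stem_pairs = stem_pairs,
                 loop_span = c(off + s + 1L, off + s + l),
                 overhang5 = off,
                 overhang3 = nchar(t$seq) - (off + 2L * s + l),
                 stem_len = s, source = t, design = design),
            class = "folded_precursor")
}

#' @export
print.folded_precursor <- function(x, ...) {
  cat(sprintf("folded precursor: %d-bp stem, loop %d-%d, 5' overhang %d nt, 3' overhang %d nt\n",
              x$stem_len, x$loop_span[1], x$loop_span[2], x$overhang5,
              x$overhang3))
  invisible(x)
}
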