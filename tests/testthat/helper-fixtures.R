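# Shared fixtures built in code. The 21-nt probe window is the common probe
# sequence used throughout the examples; everything else is generated from a
# fixed seed.

PROBE_WINDOW <- "AACUUCAGGGUCAGCUUGCCG"
probe_site <- function() list(window = PROBE_WINDOW, source_id = "probe",
                              start = 1L)

random_rna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A site with enough downstream context for long-stem designs.
random_site <- function(window_len = 21L, ctx = 10L, seed = 1L) {
  set.seed(seed)
  seq <- random_rna(window_len + ctx)
  list(window = substr(seq, 1L, window_len),
       context3 = substr(seq, window_len + 1L, window_len + ctx),
       source_id = "rand", start = 1L)
}

# Build a design with a given stem length from a fresh random window, with
# the window sized so stem + loop fits exactly (5'-arm designs).
design_with_stem <- function(stem, loop = 4L, seed = 42L) {
  set.seed(seed)
  site <- list(window = random_rna(stem + loop), source_id = "x", start = 1L)
  build_hairpin_5arm(site, stem, loop)
}

# Folded precursor with a chosen 3' overhang, via a synthesized transcript.
folded_with_overhang <- function(design, overhang3 = 2L) {
  tailseq <- if (overhang3 > 0L) random_rna(overhang3, seed = 7L) else ""
  fold_hairpin(transcript(paste0(hairpin_seq(design), tailseq)), design)
}

# Tiny miRNA annotation: two precursors with known mature coordinates.
mini_annotations <- function() {
  pre1 <- paste0(random_rna(10, seed = 11), "ACGUACGUACGUACGUACGUA",
                 random_rna(10, seed = 12))
  pre2 <- paste0(random_rna(8, seed = 13), "GGAUCCGAUCGAUCGAUCGAUCG",
                 random_rna(12, seed = 14))
  annotation_set(
    mirna = data.frame(
      name = c("mir-a", "mir-b"),
      precursor = c(pre1, pre2),
      mature_start = c(11L, 9L),
      mature_seq = c("ACGUACGUACGUACGUACGUA", "GGAUCCGAUCGAUCGAUCGAUCG"),
      stringsAsFactors = FALSE),
    trna = random_rna(70, seed = 15),
    rrna = random_rna(120, seed = 16),
    snorna = random_rna(90, seed = 17))
}
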