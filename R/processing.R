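# Processing simulator: stem-length category classification, Dicer-dependent
# dicing, Ago2 slicer-dependent maturation (pre-miR-451-like), the
# 3'-overhang-gated Ago2 loading rule, and Argonaute partitioning.

PROCESSING_CATEGORIES <- c("DICER", "AGO2_SAI", "DEAD_ZONE", "SUBOPTIMAL")

#' Classify a precursor by stem length
#'
#' Piecewise-constant mapping: stems of 21 bp and longer are Dicer substrates;
#' 16-18 bp stems are Ago2-processed (saiRNA); 19-20 bp stems fall in the
#' dead zone (bound by both Dicer and Ago2, matured by neither); stems under
#' 16 bp are suboptimal.
#'
#' @param p A `folded_precursor` or `hairpin_design` (anything with a
#'   `stem_len`), or a bare integer stem length.
#' @return One of `"DICER"`, `"AGO2_SAI"`, `"DEAD_ZONE"`, `"SUBOPTIMAL"`.
#' @export
classify_precursor <- function(p) {
  stem <- if (is.numeric(p)) as.integer(p) else p$stem_len
  if (stem >= 21L) "DICER"
  else if (stem >= 19L) "DEAD_ZONE"
  else if (stem >= 16L) "AGO2_SAI"
  else "SUBOPTIMAL"
}

#' Dicer processing of a long-stem precursor
#'
#' Emits siRNA duplexes with strand lengths 21-24 nt (capped at the stem
#' length), each with canonical 2-nt 3' overhangs; both strands are reported
#' as potential RISC cargo. Weights default to the 21/22-nt-dominated
#' distribution typical of Dicer products and are renormalized over the
#' feasible lengths.
#'
#' @param p A `folded_precursor` in the `DICER` category.
#' @param length_weights Named weights for duplex lengths `"21"`..`"24"`.
#' @return A list of class `dicer_products`: one element per duplex length
#'   with `guide`, `passenger`, `length`, `weight`, `overhang3_guide`,
#'   `overhang3_passenger`.
#' @export
dicer_process <- function(p, length_weights = c(`21` = 0.4, `22` = 0.4,
                                                `23` = 0.1, `24` = 0.1)) {
  stopifnot(inherits(p, "folded_precursor"))
  if (classify_precursor(p) != "DICER") {
    stop("dicer_process requires a DICER-category precursor (stem >= 21 bp); got ",
         classify_precursor(p), " with a ", p$stem_len, "-bp stem")
  }
  d <- p$design
  seq <- p$source$seq
  off <- p$overhang5
  lens <- as.integer(names(length_weights))
  feasible <- lens <= min(24L, d$stem_len)
  if (!any(feasible)) stop("no feasible duplex length for this stem")
  lens <- lens[feasible]
  w <- length_weights[feasible] / sum(length_weights[feasible])
  out <- lapply(seq_along(lens), function(k) {
    L <- lens[k]
    strand5 <- substr(seq, off + 1L, off + L)             # from the 5' arm
    strand3 <- substr(seq, nchar(seq) - L + 1L, nchar(seq))  # from the 3' arm
    if (d$guide_arm == "THREE") {
      guide <- strand3; passenger <- strand5
    } else {
      guide <- strand5; passenger <- strand3
    }
    list(guide = guide, passenger = passenger, length = L,
         weight = unname(w[k]), overhang3_guide = 2L,
         overhang3_passenger = 2L)
  })
  structure(out, class = "dicer_products")
}

#' Overhang-gated Ago2 loading decision
#'
#' Ago2 binding depends on the precursor's 3'-overhang length: short (<= 2 nt,
#' e.g. ribozyme-cleaved) overhangs load fully, a 4-6-nt pol III U-tail does
#' not load at all, and 3 nt is the declared half-way interpolation point.
#' The gate is a monotone non-increasing step function with configurable
#' thresholds.
#'
#' @param p A `folded_precursor` (or a bare integer 3'-overhang length).
#' @param full_max Largest overhang loading with weight 1 (default 2).
#' @param half_at Overhang length loading with weight 0.5 (default 3);
#'   anything longer loads with weight 0.
#' @return A list of class `loading_decision`: `overhang3`,
#'   `ago2_load_weight`.
#' @export
ago2_load <- function(p, full_max = 2L, half_at = 3L) {
  overhang3 <- if (is.numeric(p)) as.integer(p) else p$overhang3
  stopifnot(full_max <= half_at)
  w <- if (overhang3 <= full_max) 1 else if (overhang3 <= half_at) 0.5 else 0
  structure(list(overhang3 = overhang3, ago2_load_weight = w),
            class = "loading_decision")
}

#' Ago2 slicer-dependent processing (pre-miR-451-like)
#'
#' Ago2 slices the 3' arm between the residues paired to guide positions 11
#' and 10; the 5' product is the processing intermediate
#' (`stem + loop + (stem - 10)` nt for a precursor without a 5' overhang).
#' For saiRNA (16-18 bp stems) the intermediate is 3'-trimmed into mature
#' guides of 21 nt up to `min(24, intermediate length)`, all sharing the
#' precursor's 5' end. Dead-zone (19-20 bp) and suboptimal (< 16 bp) stems
#' yield the intermediate only — no mature species. The passenger strand is
#' destroyed by the slice, so passenger emission is structurally zero.
#'
#' @param p A `folded_precursor` (categories `AGO2_SAI`, `DEAD_ZONE` or
#'   `SUBOPTIMAL`; `DICER` precursors are an error).
#' @param mature_weights Weights for mature lengths 21..24 (default uniform);
#'   renormalized over feasible lengths.
#' @return A list of class `ago2_outcome`: `category`, `slice_bond` (the two
#'   transcript positions flanking the scissile bond), `intermediate` and
#'   `released` (`transcript`s), `matures` (data.frame `seq`, `length`,
#'   `weight`), `passenger_species` (always empty).
#' @export
ago2_process <- function(p, mature_weights = c(`21` = 1, `22` = 1,
                                               `23` = 1, `24` = 1) / 4) {
  stopifnot(inherits(p, "folded_precursor"))
  category <- classify_precursor(p)
  if (category == "DICER") {
    stop("ago2_process models slicer-dependent maturation; ",
         "DICER-category precursors (stem >= 21 bp) go through dicer_process")
  }
  d <- p$design
  s <- d$stem_len; l <- d$loop_len; off <- p$overhang5
  t <- p$source
  # 3'-arm residue paired to guide position i sits at core position
  # 2s + l + 1 - i; the scissile bond lies between the residues opposite
  # guide positions 11 and 10.
  cut <- off + 2L * s + l - 10L
  intermediate <- transcript(substr(t$seq, 1L, cut), t$ends$five_prime, "OH",
                             t$weight)
  released <- transcript(substr(t$seq, cut + 1L, nchar(t$seq)), "P",
                         t$ends$three_prime, t$weight)
  matures <- data.frame(seq = character(), length = integer(),
                        weight = numeric(), stringsAsFactors = FALSE)
  if (category == "AGO2_SAI") {
    int_len <- nchar(intermediate$seq)
    lens <- as.integer(names(mature_weights))
    feasible <- lens >= 21L & lens <= min(24L, int_len)
    if (any(feasible)) {
      lens <- lens[feasible]
      w <- mature_weights[feasible] / sum(mature_weights[feasible])
      matures <- data.frame(
        seq = substr(rep(intermediate$seq, length(lens)), 1L, lens),
        length = lens, weight = unname(w), stringsAsFactors = FALSE)
    }
  }
  structure(list(category = category,
                 slice_bond = c(upstream = cut, downstream = cut + 1L),
                 intermediate = intermediate, released = released,
                 matures = matures, passenger_species = character(0)),
            class = "ago2_outcome")
}

#' Argonaute partitioning of processing products
#'
#' Builds the Ago1-4 x species association-weight table. Dicer-made duplexes
#' load their guide into all four Agos with equal weight and the passenger
#' into Ago1-3 (Ago4 signal is configurable and defaults to 0, matching its
#' below-detection expression). Ago2-dependent (saiRNA) outcomes place the
#' intermediate and the mature guide on Ago2 only; the slicing-incompetent
#' Ago1/3/4 associate with the unprocessed precursor. An optional residual
#' Ago3 mature weight (default 0) models its weak cleavage activity. Forcing
#' `ago2_active = FALSE` (Ago2-knockout mode) zeroes the Ago2 row, leaving no
#' mature saiRNA species anywhere.
#'
#' @param p A `folded_precursor`.
#' @param outcome The matching `dicer_products` or `ago2_outcome`.
#' @param ago4_passenger Passenger weight on Ago4 for duplex outcomes.
#' @param ago3_residual_mature Residual mature-guide weight on Ago3 for
#'   saiRNA outcomes.
#' @param ago2_active Set `FALSE` to simulate an Ago2 knockout.
#' @return A 4 x 4 numeric matrix of class `ago_partition`; rows `Ago1`-`Ago4`,
#'   columns `precursor`, `intermediate`, `mature_guide`, `mature_passenger`.
#' @export
ago_partition <- function(p, outcome, ago4_passenger = 0,
                          ago3_residual_mature = 0, ago2_active = TRUE) {
  tab <- matrix(0, nrow = 4L, ncol = 4L,
                dimnames = list(paste0("Ago", 1:4),
                                c("precursor", "intermediate", "mature_guide",
                                  "mature_passenger")))
  if (inherits(outcome, "dicer_products")) {
    tab[, "mature_guide"] <- 0.25
    tab[1:3, "mature_passenger"] <- 1 / 3
    tab["Ago4", "mature_passenger"] <- ago4_passenger
  } else if (inherits(outcome, "ago2_outcome")) {
    gate <- ago2_load(p)$ago2_load_weight
    tab[c("Ago1", "Ago3", "Ago4"), "precursor"] <- 1
    tab["Ago2", "intermediate"] <- gate
    if (nrow(outcome$matures) > 0L) {
      tab["Ago2", "mature_guide"] <- gate
      tab["Ago3", "mature_guide"] <- ago3_residual_mature * gate
    }
  } else stop("outcome must be dicer_products or an ago2_outcome")
  if (!ago2_active) tab["Ago2", ] <- 0
  structure(tab, class = c("ago_partition", class(tab)))
}

#' Simulate the full biogenesis of a designed hairpin
#'
#' Composes the whole pipeline: cassette assembly, transcription (pol III
#' U-tail ensemble or T7 run-off), ribozyme self-cleavage, folding,
#' stem-length classification, Dicer or Ago2 processing behind the
#' 3'-overhang loading gate, and Ago partitioning. Deterministic given the
#' configuration: the transcript ensemble is propagated by weight, never
#' sampled.
#'
#' Species weights are interpreted as observable steady-state fractions of
#' one transcribed precursor equivalent: remaining precursor weight plus
#' mature weights sum to 1 for saiRNA, and the intermediate is reported
#' additionally as a transient observable with the loaded weight. In the
#' dead zone the intermediate is terminal, so precursor plus intermediate
#' sum to 1 instead. A small
#' `leak` fraction of gate-blocked precursors is 3'-trimmed to a 2-nt
#' overhang (the minor short isoform seen for uncleaved saiRNA) and processed.
#'
#' @param design A `hairpin_design`.
#' @param ribozyme `"WT"`, `"C75U"` or `"none"`.
#' @param promoter `"H1"`, `"U6"` or `"T7"`.
#' @param spacer Spacer between the 3' arm and the ribozyme (default `"UU"`).
#' @param tail_weights Pol III U-tail (4/5/6 nt) weights, default uniform.
#' @param leak Fraction of unloadable precursor rescued by 3' trimming
#'   (default 0.05).
#' @param dicer_weights,mature_weights Passed to [dicer_process()] /
#'   [ago2_process()].
#' @param ago2_active Set `FALSE` for Ago2-knockout mode.
#' @param ago4_passenger,ago3_residual_mature Passed to [ago_partition()].
#' @return A list of class `processing_outcome`: `category`, `species`
#'   (data.frame `species`, `class`, `seq`, `length`, `weight`), `ago_table`,
#'   `loading`, `design`, `config`.
#' @export
simulate_processing <- function(design, ribozyme = c("WT", "C75U", "none"),
                                promoter = c("H1", "U6", "T7"), spacer = "UU",
                                tail_weights = c(1, 1, 1) / 3, leak = 0.05,
                                dicer_weights = c(`21` = 0.4, `22` = 0.4,
                                                  `23` = 0.1, `24` = 0.1),
                                mature_weights = c(`21` = 1, `22` = 1,
                                                   `23` = 1, `24` = 1) / 4,
                                ago2_active = TRUE, ago4_passenger = 0,
                                ago3_residual_mature = 0) {
  ribozyme <- match.arg(ribozyme)
  promoter <- match.arg(promoter)
  cassette <- attach_ribozyme(design, ribozyme, spacer, promoter)
  transcripts <- if (promoter == "T7") list(transcribe_t7(cassette))
                 else transcribe_pol3(cassette, tail_weights)
  # Ribozyme cleavage per ensemble member; the upstream product carries the
  # hairpin (and equals the intact input when the ribozyme is inactive).
  precursors <- lapply(transcripts, function(t) {
    if (!is.null(cassette$ribozyme)) ribozyme_cleave(t, cassette$ribozyme)$upstream
    else t
  })
  folded <- lapply(precursors, fold_hairpin, design = design)
  category <- classify_precursor(folded[[1]])

  rows <- list()
  add <- function(species, class, seq, weight) {
    rows[[length(rows) + 1L]] <<- data.frame(
      species = species, class = class, seq = seq, length = nchar(seq),
      weight = weight, stringsAsFactors = FALSE)
  }
  outcome_obj <- if (category == "DICER") NULL
                 else ago2_process(folded[[1]], mature_weights)
  add_matures <- function(out, w) {
    for (k in seq_len(nrow(out$matures))) {
      add(paste0("mature_guide_", out$matures$length[k]), "mature_guide",
          out$matures$seq[k], w * out$matures$weight[k])
    }
  }
  for (p in folded) {
    w <- p$source$weight
    if (category == "DICER") {
      prods <- dicer_process(p, dicer_weights)
      outcome_obj <- prods
      for (dx in prods) {
        add(paste0("mature_guide_", dx$length), "mature_guide",
            dx$guide, w * dx$weight)
        add(paste0("mature_passenger_", dx$length), "mature_passenger",
            dx$passenger, w * dx$weight)
      }
    } else {
      gate <- if (ago2_active) ago2_load(p)$ago2_load_weight else 0
      loaded_w <- w * gate
      leak_w <- if (gate == 0 && ago2_active) w * leak else 0
      if (loaded_w > 0) {
        out <- ago2_process(p, mature_weights)
        outcome_obj <- out
        add("intermediate", "intermediate", out$intermediate$seq, loaded_w)
        add_matures(out, loaded_w)
      }
      if (leak_w > 0) {
        # minor short isoform: 3' end trimmed back to a 2-nt overhang
        core_end <- p$overhang5 + 2L * design$stem_len + design$loop_len
        trimmed <- transcript(substr(p$source$seq, 1L, core_end + 2L),
                              p$source$ends$five_prime, "OH", leak_w)
        pt <- fold_hairpin(trimmed, design)
        out <- ago2_process(pt, mature_weights)
        add("intermediate", "intermediate", out$intermediate$seq, leak_w)
        add_matures(out, leak_w)
      }
      remaining <- w - loaded_w - leak_w
      if (remaining > 1e-12) {
        add("precursor", "precursor", p$source$seq, remaining)
      }
    }
  }
  species <- do.call(rbind, rows)
  # Aggregate identical species (same name + sequence) across tail variants.
  key <- paste(species$species, species$seq)
  agg <- stats::aggregate(weight ~ key, data = cbind(species, key = key), sum)
  species <- species[!duplicated(key), c("species", "class", "seq", "length")]
  species$weight <- agg$weight[match(paste(species$species, species$seq),
                                     agg$key)]
  species <- species[order(species$class, species$length), , drop = FALSE]
  rownames(species) <- NULL
  ago <- ago_partition(folded[[1]], outcome_obj, ago4_passenger,
                       ago3_residual_mature, ago2_active)
  structure(list(category = category, species = species, ago_table = ago,
                 loading = data.frame(
                   overhang3 = vapply(folded, function(p) p$overhang3, integer(1)),
                   weight = vapply(folded, function(p) p$source$weight, numeric(1)),
                   load = vapply(folded, function(p)
                     ago2_load(p)$ago2_load_weight, numeric(1))),
                 design = design,
                 config = list(ribozyme = ribozyme, promoter = promoter,
                               spacer = spacer, leak = leak,
                               ago2_active = ago2_active)),
            class = "processing_outcome")
}

#' @export
print.processing_outcome <- function(x, ...) {
  cat(sprintf("processing outcome: category %s (%d-bp stem), %s promoter, ribozyme %s\n",
              x$category, x$design$stem_len, x$config$promoter,
              x$config$ribozyme))
  print(x$species[, c("species", "length", "weight")], row.names = FALSE)
  invisible(x)
}
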