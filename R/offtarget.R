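# Off-target analysis: 2-7 seed extraction, exact reverse-complement seed
# scanning of 3' UTR sets, differential-expression attribution in the style
# of guide/passenger seed-dependent gene counts, antisense-transcript risk
# flags, and a synthetic transcriptome generator with planted effects.

#' Extract the seed (positions 2-7) of a small-RNA strand
#'
#' @param strand Guide or passenger sequence (>= 7 nt), 5'->3'.
#' @param origin `"GUIDE"` or `"PASSENGER"`.
#' @return A list of class `seed`: `hexamer`, `origin`, `positions`.
#' @export
extract_seed <- function(strand, origin = c("GUIDE", "PASSENGER")) {
  origin <- match.arg(origin)
  strand <- dna_to_rna(validate_nucseq(strand))
  if (nchar(strand) < 7L) stop("strand must be at least 7 nt to have a 2-7 seed")
  structure(list(hexamer = substr(strand, 2L, 7L), origin = origin,
                 positions = 2:7),
            class = "seed")
}

# Count (possibly overlapping) exact occurrences of `motif` in `subject`.
count_sites <- function(motif, subject) {
  hits <- gregexpr(paste0("(?=", motif, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Scan 3' UTRs for seed-complementary sites
#'
#' Counts exact occurrences of the reverse complement of the seed hexamer in
#' each UTR (overlapping occurrences included), mirroring a
#' reverse-complementarity search of annotated 3' UTRs.
#'
#' @param seed A [extract_seed()] result (or a bare 6-nt hexamer).
#' @param utrs Data.frame with columns `id`, `seq` ([read_fasta()] output),
#'   DNA or RNA alphabet.
#' @return A list of class `seed_match_report`: `per_utr` (data.frame `id`,
#'   `n_sites`, `positions` as comma-separated string), `genes_with_site`,
#'   `total_sites`, `seed`.
#' @export
scan_seed_matches <- function(seed, utrs) {
  hex <- if (inherits(seed, "seed")) seed$hexamer else
    validate_nucseq(seed)
  if (nchar(hex) != 6L) stop("seed hexamer must be 6 nt")
  if (is.null(utrs) || nrow(utrs) == 0L) {
    per <- data.frame(id = character(), n_sites = integer(),
                      positions = character(), stringsAsFactors = FALSE)
    return(structure(list(per_utr = per, genes_with_site = 0L,
                          total_sites = 0L, seed = seed),
                     class = "seed_match_report"))
  }
  site <- revcomp(hex, "RNA")
  hits <- lapply(toupper(dna_to_rna(utrs$seq)), function(u) count_sites(site, u))
  n <- vapply(hits, length, integer(1))
  per <- data.frame(id = utrs$id, n_sites = n,
                    positions = vapply(hits, paste, character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  structure(list(per_utr = per, genes_with_site = sum(n > 0L),
                 total_sites = sum(n), seed = seed),
            class = "seed_match_report")
}

#' Attribute differential expression to guide / passenger seeds
#'
#' Filters genes to control FPKM >= `fpkm_min`, classifies up/down regulation
#' by the treated/control ratio against `fc` (ties at the threshold
#' included), and intersects the downregulated set with seed-site presence in
#' each gene's 3' UTR — independently for the guide and the passenger seed, so
#' a gene may appear in both rows. Passing `passenger_seed = NULL` (a saiRNA,
#' which emits no passenger) reports `NA` for the passenger row.
#'
#' @param expr Data.frame with columns `id`, `fpkm_control`, `fpkm_treated`.
#' @param guide_seed A `seed` (or 6-nt hexamer) for the guide strand.
#' @param passenger_seed As above for the passenger, or `NULL`.
#' @param utrs UTR data.frame (`id`, `seq`); ids shared with `expr`. Genes
#'   lacking a UTR count toward up/down but are excluded from seed
#'   attribution (their number is reported).
#' @param fpkm_min Expression filter on control FPKM (default 10).
#' @param fc Fold-change threshold (default 1.5).
#' @param pseudocount Added to both FPKM values before the ratio (default 0;
#'   the FPKM filter removes control zeros).
#' @return A list of class `attribution_table` with counts `upregulated`,
#'   `downregulated`, `down_guide_seed`, `down_passenger_seed`,
#'   `genes_no_utr`, and the underlying per-gene table in `detail`.
#' @export
attribute_deg <- function(expr, guide_seed, passenger_seed = NULL, utrs,
                          fpkm_min = 10, fc = 1.5, pseudocount = 0) {
  stopifnot(all(c("id", "fpkm_control", "fpkm_treated") %in% names(expr)))
  if (any(expr$fpkm_control < 0 | expr$fpkm_treated < 0)) {
    stop("FPKM values must be non-negative")
  }
  keep <- expr$fpkm_control >= fpkm_min
  e <- expr[keep, , drop = FALSE]
  ratio <- (e$fpkm_treated + pseudocount) / (e$fpkm_control + pseudocount)
  eps <- 1e-9  # ties at the threshold count as changed
  up <- ratio >= fc * (1 - eps)
  down <- ratio <= (1 / fc) * (1 + eps)
  has_utr <- e$id %in% utrs$id
  seed_hits <- function(seed) {
    if (is.null(seed)) return(NULL)
    rep_ <- scan_seed_matches(seed, utrs)
    ids <- rep_$per_utr$id[rep_$per_utr$n_sites > 0L]
    e$id %in% ids
  }
  g_hit <- seed_hits(guide_seed)
  p_hit <- seed_hits(passenger_seed)
  n_no_utr <- sum(down & !has_utr)
  if (n_no_utr > 0L) {
    message(n_no_utr, " downregulated gene(s) lack a UTR and are excluded ",
            "from seed attribution")
  }
  detail <- data.frame(id = e$id, ratio = ratio, up = up, down = down,
                       has_utr = has_utr,
                       guide_seed_site = if (is.null(g_hit)) NA else g_hit & has_utr,
                       passenger_seed_site = if (is.null(p_hit)) NA else p_hit & has_utr,
                       stringsAsFactors = FALSE)
  structure(list(
    upregulated = sum(up),
    downregulated = sum(down),
    down_guide_seed = if (is.null(g_hit)) NA_integer_ else
      sum(down & has_utr & g_hit),
    down_passenger_seed = if (is.null(p_hit)) NA_integer_ else
      sum(down & has_utr & p_hit),
    genes_no_utr = n_no_utr,
    fpkm_min = fpkm_min, fc = fc, detail = detail),
    class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("DEG attribution (control FPKM >= %g, fold change >= %g):\n",
              x$fpkm_min, x$fc))
  cat(sprintf("  upregulated genes:                     %d\n", x$upregulated))
  cat(sprintf("  downregulated genes:                   %d\n", x$downregulated))
  cat(sprintf("  guide seed-dependent (2-7) down:       %s\n",
              format(x$down_guide_seed)))
  cat(sprintf("  passenger seed-dependent (2-7) down:   %s\n",
              format(x$down_passenger_seed)))
  invisible(x)
}

#' Flag antisense transcripts at risk of passenger-strand cleavage
#'
#' A Dicer-processed shRNA loads its passenger strand (the sense sequence)
#' into RISC, which can slice any transcript carrying a perfectly
#' complementary 21-nt site — in particular antisense transcripts overlapping
#' the target locus. saiRNA designs eliminate the passenger strand during
#' Ago2 maturation, so they always return no risk.
#'
#' @param outcome A `processing_outcome` from [simulate_processing()].
#' @param antisense_transcripts Data.frame (`id`, `seq`) of antisense
#'   transcripts to screen; empty input gives an empty report.
#' @return Data.frame with columns `id`, `risk` (`"PERFECT_MATCH"` or
#'   `"NONE"`), `passenger_species`.
#' @export
antisense_risk <- function(outcome, antisense_transcripts) {
  stopifnot(inherits(outcome, "processing_outcome"))
  if (is.null(antisense_transcripts) || nrow(antisense_transcripts) == 0L) {
    return(data.frame(id = character(), risk = character(),
                      passenger_species = character(),
                      stringsAsFactors = FALSE))
  }
  pass <- outcome$species[outcome$species$class == "mature_passenger", ,
                          drop = FALSE]
  flags <- vapply(dna_to_rna(toupper(antisense_transcripts$seq)), function(tx) {
    if (nrow(pass) == 0L) return("NONE")
    for (p in pass$seq) {
      if (nchar(p) < 21L) next
      site <- revcomp(substr(p, 1L, 21L), "RNA")
      if (grepl(site, tx, fixed = TRUE)) return("PERFECT_MATCH")
    }
    "NONE"
  }, character(1), USE.NAMES = FALSE)
  data.frame(id = antisense_transcripts$id, risk = flags,
             passenger_species = if (nrow(pass) == 0L) "" else
               paste(unique(pass$species), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic transcriptome with planted seed-target effects
#'
#' Builds `n_genes` random 3' UTRs that are free of guide- and passenger-seed
#' sites (rejection sampling), plants exactly one seed-complementary site into
#' each designated target gene, and pairs the UTR set with an expression
#' table in which planted genes are downregulated by `fold_change` (all
#' control FPKMs pass the standard filter). Regeneration with the same seed
#' is byte-identical, and [attribute_deg()] recovers every planted effect on
#' the noise-free output.
#'
#' @param n_genes Number of genes.
#' @param guide_seed Seed (or 6-nt hexamer) whose sites are planted in guide
#'   targets and excluded elsewhere.
#' @param passenger_seed Optional second seed for passenger targets.
#' @param n_guide_targets,n_passenger_targets Numbers of planted target genes
#'   (disjoint sets).
#' @param fold_change Downregulation factor for planted genes (default 2).
#' @param utr_len_range UTR length range in nt (default 200-400).
#' @param noise_sd Log2-scale expression noise on non-planted genes
#'   (default 0 = noise-free).
#' @param rng_seed Integer seed; the generator is fully reproducible.
#' @return A list of class `synthetic_transcriptome`: `utrs` (data.frame
#'   `id`, `seq`), `expr` (`id`, `fpkm_control`, `fpkm_treated`), `planted`
#'   (data.frame `id`, `origin`, `fold_change`), `rng_seed`.
#' @export
synth_transcriptome <- function(n_genes, guide_seed,
                                passenger_seed = NULL,
                                n_guide_targets = 0L,
                                n_passenger_targets = 0L,
                                fold_change = 2,
                                utr_len_range = c(200L, 400L),
                                noise_sd = 0, rng_seed = 1L) {
  if (n_guide_targets + n_passenger_targets > n_genes) {
    stop("more planted targets than genes")
  }
  if (n_passenger_targets > 0L && is.null(passenger_seed)) {
    stop("passenger targets requested but no passenger seed given")
  }
  hex_of <- function(s) if (inherits(s, "seed")) s$hexamer else
    dna_to_rna(validate_nucseq(s))
  g_hex <- hex_of(guide_seed)
  p_hex <- if (is.null(passenger_seed)) NULL else hex_of(passenger_seed)
  sites <- c(revcomp(g_hex, "RNA"),
             if (!is.null(p_hex)) revcomp(p_hex, "RNA"))
  if (min(utr_len_range) < 20L) stop("UTRs must be at least 20 nt")
  if (n_genes == 0L) {
    return(structure(list(
      utrs = data.frame(id = character(), seq = character(),
                        stringsAsFactors = FALSE),
      expr = data.frame(id = character(), fpkm_control = numeric(),
                        fpkm_treated = numeric(), stringsAsFactors = FALSE),
      planted = data.frame(id = character(), origin = character(),
                           fold_change = numeric(), stringsAsFactors = FALSE),
      rng_seed = rng_seed), class = "synthetic_transcriptome"))
  }
  set.seed(rng_seed)
  rand_utr <- function(len, forbidden) {
    for (try in 1:200) {
      u <- paste(sample(RNA_BASES, len, replace = TRUE), collapse = "")
      if (!any(vapply(forbidden, grepl, logical(1), x = u, fixed = TRUE))) {
        return(u)
      }
    }
    stop("could not sample a UTR free of seed sites; shorten the UTRs")
  }
  lens <- sample(seq(utr_len_range[1], utr_len_range[2]), n_genes,
                 replace = TRUE)
  utr_seqs <- vapply(lens, rand_utr, character(1), forbidden = sites)
  ids <- sprintf("gene%04d", seq_len(n_genes))
  # Plant exactly one site per target, replacing a central window so no
  # unintended extra site is created (verified, resample on collision).
  idx <- sample(n_genes, n_guide_targets + n_passenger_targets)
  g_idx <- idx[seq_len(n_guide_targets)]
  p_idx <- setdiff(idx, g_idx)
  plant <- function(u, site) {
    for (try in 1:200) {
      pos <- sample(nchar(u) - 5L, 1L)
      cand <- paste0(substr(u, 1L, pos - 1L), site,
                     substr(u, pos + 6L, nchar(u)))
      n_hit <- length(count_sites(site, cand))
      others <- setdiff(sites, site)
      clean <- !any(vapply(others, grepl, logical(1), x = cand, fixed = TRUE))
      if (n_hit == 1L && clean) return(cand)
    }
    stop("could not plant a unique seed site")
  }
  for (i in g_idx) utr_seqs[i] <- plant(utr_seqs[i], sites[1])
  for (i in p_idx) utr_seqs[i] <- plant(utr_seqs[i], sites[2])
  fpkm_control <- 10 + stats::rlnorm(n_genes, meanlog = 3, sdlog = 1)
  fpkm_treated <- fpkm_control
  if (noise_sd > 0) {
    fpkm_treated <- fpkm_treated * 2^stats::rnorm(n_genes, 0, noise_sd)
  }
  fpkm_treated[c(g_idx, p_idx)] <- fpkm_control[c(g_idx, p_idx)] / fold_change
  planted <- data.frame(
    id = ids[c(g_idx, p_idx)],
    origin = rep(c("GUIDE", "PASSENGER"), c(length(g_idx), length(p_idx))),
    fold_change = fold_change, stringsAsFactors = FALSE)
  structure(list(
    utrs = data.frame(id = ids, seq = utr_seqs, stringsAsFactors = FALSE),
    expr = data.frame(id = ids, fpkm_control = fpkm_control,
                      fpkm_treated = fpkm_treated, stringsAsFactors = FALSE),
    planted = planted, rng_seed = rng_seed),
    class = "synthetic_transcriptome")
}
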