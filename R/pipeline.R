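# Pipeline orchestration and configuration: a YAML-configurable end-to-end
# run (design -> cassette -> simulate -> offtarget / profile) with versioned,
# reproducible artifacts. A thin command-line wrapper over run_pipeline()
# ships in inst/cli/sairna-pipeline.R.

PIPELINE_STAGES <- c("design", "simulate", "offtarget", "profile")

default_run_config <- function() {
  list(
    seed = 1L,
    stages = PIPELINE_STAGES,
    target_fasta = NULL,        # required for the design stage
    mode = "sairna",            # sairna | shrna_classic | shrna_5arm
    stem_len = 17L, loop_len = 4L, mismatch_base = "C",
    gc_min = 0.25, gc_max = 0.75, max_u_run = 4L,
    n_candidates = 5L,          # designs carried into later stages
    vector = "H1_pSilencer", make_oligos = TRUE,
    ribozyme = "WT", promoter = "H1", spacer = "UU", terminator_len = 6L,
    leak = 0.05, ago2_active = TRUE,
    utrs_fasta = NULL, expr_tsv = NULL, fpkm_min = 10, fc = 1.5,
    fastq = NULL, adaptor = "UCGUAUGCCGUCUUCUGCUUGU", min_len = 19L,
    synth_depth = 0L            # > 0: profile synthetic reads of the outcome
  )
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML file, overlays it on the package defaults, and validates
#' types and ranges before any stage runs.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    config[names(user)] <- user
  }
  config[names(overrides)] <- overrides
  config$seed <- as.integer(config$seed)
  config$stages <- match.arg(config$stages, PIPELINE_STAGES,
                             several.ok = TRUE)
  config$mode <- match.arg(config$mode,
                           c("sairna", "shrna_classic", "shrna_5arm"))
  config$ribozyme <- match.arg(config$ribozyme, c("WT", "C75U", "none"))
  config$promoter <- match.arg(config$promoter, c("H1", "U6", "T7"))
  if (!config$vector %in% names(CLONING_VECTORS)) {
    stop("unknown vector: ", config$vector)
  }
  structure(config, class = "run_config")
}

write_tsv_artifact <- function(df, path, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sairna ", as.character(utils::packageVersion("sairna"))),
    paste0("# config_hash ", config_hash)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full design-to-profile pipeline
#'
#' Executes the configured stages in order, writing one artifact per stage
#' into `out_dir`: `designs.tsv` (+ `oligos.tsv`), `outcome.json`,
#' `offtarget.tsv`, `profile.tsv`, plus the resolved configuration
#' (`config.yaml`). Every TSV carries a header with the package version and
#' the config hash; given identical config and seed the outputs are
#' byte-identical. Stage failures abort with a stage-named error.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  artifacts <- list(config = cfg_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  designs <- NULL
  outcome <- NULL

  if ("design" %in% config$stages) {
    designs <- stage("design", {
      if (is.null(config$target_fasta)) stop("target_fasta not set")
      if (!file.exists(config$target_fasta)) {
        stop("target FASTA not found: ", config$target_fasta)
      }
      mrna <- read_fasta(config$target_fasta)[1, ]
      cons <- design_constraints(
        stem_len = config$stem_len, loop_len = config$loop_len,
        mismatch_base = config$mismatch_base, gc_min = config$gc_min,
        gc_max = config$gc_max, max_u_run = config$max_u_run)
      sites <- scan_target_sites(mrna, cons)
      if (nrow(sites) == 0L) stop("no candidate sites pass the filters")
      builder <- switch(config$mode,
        sairna = function(s) build_sairna(s, config$stem_len,
                                          config$loop_len,
                                          config$mismatch_base),
        shrna_classic = function(s) build_shrna_classic(s),
        shrna_5arm = function(s) build_shrna_5arm(s, config$stem_len,
                                                  config$loop_len,
                                                  config$mismatch_base))
      built <- lapply(seq_len(nrow(sites)), function(i) builder(sites[i, ]))
      ranked <- rank_candidates(built)
      top <- utils::head(attr(ranked, "designs"), config$n_candidates)
      tab <- data.frame(
        rank = seq_along(top),
        source_id = vapply(top, function(d) d$site$source_id, character(1)),
        start = vapply(top, function(d) as.integer(d$site$start), integer(1)),
        window = vapply(top, function(d) d$site$window, character(1)),
        guide = vapply(top, function(d) d$guide, character(1)),
        hairpin = vapply(top, hairpin_seq, character(1)),
        asymmetry = vapply(top, asymmetry_score, numeric(1)),
        stringsAsFactors = FALSE)
      artifacts$designs <- write_tsv_artifact(
        tab, file.path(out_dir, "designs.tsv"), config_hash)
      if (isTRUE(config$make_oligos)) {
        pairs <- lapply(top, function(d) {
          cas <- attach_ribozyme(d, config$ribozyme, config$spacer,
                                 if (config$promoter == "T7") "T7" else config$promoter,
                                 config$terminator_len)
          make_cloning_oligos(cas, config$vector)
        })
        otab <- data.frame(
          rank = seq_along(pairs),
          vector = config$vector,
          top = vapply(pairs, function(p) p$top, character(1)),
          bottom = vapply(pairs, function(p) p$bottom, character(1)),
          stringsAsFactors = FALSE)
        artifacts$oligos <- write_tsv_artifact(
          otab, file.path(out_dir, "oligos.tsv"), config_hash)
      }
      top
    })
  }

  if ("simulate" %in% config$stages) {
    outcome <- stage("simulate", {
      if (is.null(designs)) stop("simulate requires the design stage")
      out <- simulate_processing(
        designs[[1]], ribozyme = config$ribozyme,
        promoter = config$promoter, spacer = config$spacer,
        leak = config$leak, ago2_active = config$ago2_active)
      path <- file.path(out_dir, "outcome.json")
      jsonlite::write_json(list(
        version = as.character(utils::packageVersion("sairna")),
        config_hash = config_hash,
        category = out$category,
        species = out$species,
        ago_table = as.data.frame(unclass(out$ago_table)),
        loading = out$loading), path, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      artifacts$outcome <- path
      out
    })
  }

  if ("offtarget" %in% config$stages) {
    stage("offtarget", {
      if (is.null(outcome)) stop("offtarget requires the simulate stage")
      if (is.null(config$utrs_fasta) || is.null(config$expr_tsv)) {
        stop("utrs_fasta and expr_tsv must be set")
      }
      utrs <- read_fasta(config$utrs_fasta)
      expr <- utils::read.delim(config$expr_tsv, comment.char = "#",
                                stringsAsFactors = FALSE)
      guides <- outcome$species[outcome$species$class == "mature_guide", ,
                                drop = FALSE]
      if (nrow(guides) == 0L) stop("no mature guide species in the outcome")
      major <- guides$seq[which.max(guides$weight)]
      g_seed <- extract_seed(major, "GUIDE")
      pass <- outcome$species[outcome$species$class == "mature_passenger", ,
                              drop = FALSE]
      p_seed <- if (nrow(pass) == 0L) NULL else
        extract_seed(pass$seq[which.max(pass$weight)], "PASSENGER")
      att <- attribute_deg(expr, g_seed, p_seed, utrs,
                           fpkm_min = config$fpkm_min, fc = config$fc)
      tab <- data.frame(
        metric = c("upregulated", "downregulated", "down_guide_seed",
                   "down_passenger_seed", "genes_no_utr"),
        value = c(att$upregulated, att$downregulated, att$down_guide_seed,
                  att$down_passenger_seed, att$genes_no_utr),
        stringsAsFactors = FALSE)
      artifacts$offtarget <- write_tsv_artifact(
        tab, file.path(out_dir, "offtarget.tsv"), config_hash)
    })
  }

  if ("profile" %in% config$stages) {
    stage("profile", {
      reads <- if (!is.null(config$fastq)) {
        if (!file.exists(config$fastq)) stop("FASTQ not found: ", config$fastq)
        read_fastq(config$fastq)
      } else if (config$synth_depth > 0L) {
        if (is.null(outcome)) stop("synthetic profiling requires the simulate stage")
        synth_reads(outcome, config$synth_depth, config$adaptor,
                    rng_seed = config$seed)
      } else stop("set fastq or synth_depth")
      rs <- preprocess_reads(reads, config$adaptor, config$min_len)
      construct <- if (!is.null(designs)) hairpin_seq(designs[[1]])
                   else character()
      het <- if (length(construct) > 0L) end_heterogeneity(rs, construct)
             else NULL
      tab <- rs$reads
      artifacts$profile <- write_tsv_artifact(
        tab, file.path(out_dir, "profile.tsv"), config_hash)
      if (!is.null(het) && nrow(het$isoforms) > 0L) {
        artifacts$isoforms <- write_tsv_artifact(
          het$isoforms, file.path(out_dir, "isoforms.tsv"), config_hash)
      }
    })
  }
  invisible(artifacts)
}
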