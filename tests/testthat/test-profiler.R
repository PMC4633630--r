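# Read preprocessing, sequential categorization, miRNA counting,
# normalization, end heterogeneity, and the synthetic read generator.

ADAPTOR <- "UCGUAUGCCGUCUUCUGCUUGU"

test_that("preprocessing clips, filters by length, and collapses", {
  insert21 <- random_rna(21, seed = 60)
  insert18 <- random_rna(18, seed = 61)
  reads <- c(paste0(insert21, ADAPTOR),          # kept, clipped to 21
             paste0(insert21, ADAPTOR),          # duplicate, collapsed
             paste0(insert18, ADAPTOR),          # too short after clipping
             random_rna(40, seed = 62),          # no adaptor: removed
             paste0(insert21, substr(ADAPTOR, 1, 8)))  # partial terminal adaptor
  rs <- preprocess_reads(reads, ADAPTOR)
  expect_equal(rs$total_raw, 5L)
  expect_equal(rs$total_useful, 3L)
  expect_equal(nrow(rs$reads), 1L)
  expect_equal(rs$reads$seq, insert21)
  expect_equal(rs$reads$count, 3L)
  expect_error(preprocess_reads(reads, "ACGU"), "at least 6")
})

test_that("sequential categorization is exhaustive, disjoint, and ordered", {
  ann <- mini_annotations()
  construct <- hairpin_seq(build_sairna(probe_site()))
  mat1 <- ann$mirna$mature_seq[1]
  reads <- c(
    paste0(substr(construct, 1, 21), ADAPTOR),      # construct
    paste0(mat1, ADAPTOR),                          # miRNA
    paste0(substr(ann$trna, 1, 20), ADAPTOR),       # tRNA
    paste0(substr(ann$rrna, 5, 28), ADAPTOR),       # rRNA
    paste0(substr(ann$snorna, 3, 24), ADAPTOR),     # snoRNA
    paste0(random_rna(22, seed = 63), ADAPTOR))     # unmapped
  rs <- preprocess_reads(reads, ADAPTOR)
  cc <- classify_reads(rs, ann, construct)
  expect_equal(sum(cc$counts), rs$total_useful)
  expect_equal(unname(cc$counts[c("construct", "mirna", "trna", "rrna",
                                  "snorna", "unmapped")]),
               c(1L, 1L, 1L, 1L, 1L, 1L))
  # sequential precedence: a read present in both miRNA and rRNA references
  # counts as miRNA
  ann2 <- ann
  ann2$rrna <- c(ann2$rrna, mat1)
  cc2 <- classify_reads(preprocess_reads(paste0(mat1, ADAPTOR), ADAPTOR),
                        ann2, character())
  expect_equal(unname(cc2$counts["mirna"]), 1L)
  expect_equal(unname(cc2$counts["rrna"]), 0L)
  # construct-only library: 100% construct class
  rs3 <- preprocess_reads(rep(paste0(substr(construct, 3, 26), ADAPTOR), 10),
                          ADAPTOR)
  cc3 <- classify_reads(rs3, ann, construct)
  expect_equal(unname(cc3$counts["construct"]), 10L)
  # empty references warn and leave everything unmapped
  expect_warning(
    cc4 <- classify_reads(rs3, annotation_set(), character()), "empty")
  expect_equal(unname(cc4$counts["unmapped"]), 10L)
})

test_that("classification equals a brute-force substring search", {
  ann <- mini_annotations()
  construct <- hairpin_seq(build_sairna(probe_site()))
  refs <- list(construct = construct, mirna = ann$mirna$precursor,
               trna = ann$trna, rrna = ann$rrna, snorna = ann$snorna,
               other = character())
  brute_class <- function(read) {
    for (cl in names(refs)) {
      for (r in refs[[cl]]) {
        if (grepl(read, r, fixed = TRUE) ||
            grepl(revcomp(read, "RNA"), r, fixed = TRUE)) return(cl)
      }
    }
    "unmapped"
  }
  set.seed(64)
  pool <- c(vapply(1:10, function(i) {
    src <- sample(unlist(refs), 1)
    st <- sample(max(1, nchar(src) - 21), 1)
    substr(src, st, st + 20)
  }, character(1)), replicate(5, random_rna(21)))
  rs <- preprocess_reads(paste0(pool, ADAPTOR), ADAPTOR)
  cc <- classify_reads(rs, ann, construct)
  for (k in seq_len(nrow(cc$assignment))) {
    expect_equal(cc$assignment$class[k], brute_class(cc$assignment$seq[k]))
  }
})

test_that("miRNA counting anchors the 5' end and allows +/-2 templated 3' ends", {
  ann <- mini_annotations()
  mi <- ann$mirna[1, ]
  mat <- mi$mature_seq
  pre <- mi$precursor
  st <- mi$mature_start
  mk <- function(s) preprocess_reads(paste0(s, ADAPTOR), ADAPTOR)
  # exact mature sequence counts
  expect_equal(unname(count_mirna(mk(mat), ann)["mir-a"]), 1L)
  # +1 templated 3' addition counts
  plus1 <- substr(pre, st, st + nchar(mat))
  expect_equal(unname(count_mirna(mk(plus1), ann)["mir-a"]), 1L)
  # -2 3' deletion counts
  minus2 <- substr(mat, 1, nchar(mat) - 2)
  expect_equal(unname(count_mirna(mk(minus2), ann)["mir-a"]), 1L)
  # -3 is outside the window
  minus3 <- substr(mat, 1, nchar(mat) - 3)
  expect_equal(unname(count_mirna(mk(minus3), ann)["mir-a"]), 0L)
  # +1 untemplated 3' addition does not count
  bad_nt <- setdiff(c("A", "C", "G", "U"),
                    substr(pre, st + nchar(mat), st + nchar(mat)))[1]
  expect_equal(unname(count_mirna(mk(paste0(mat, bad_nt)), ann)["mir-a"]), 0L)
  # 5'-shifted read does not count
  shifted <- substr(pre, st + 1, st + nchar(mat))
  expect_equal(unname(count_mirna(mk(shifted), ann)["mir-a"]), 0L)
})

test_that("per-million normalization sums to exactly 1e6 and is scale invariant", {
  expect_equal(unname(normalize_mirna(c(a = 30, b = 70))),
               c(300000, 700000))
  expect_equal(unname(normalize_mirna(c(only = 12))), 1e6)
  set.seed(65)
  counts <- stats::setNames(sample(1:500, 20), paste0("m", 1:20))
  expect_equal(sum(normalize_mirna(counts)), 1e6)
  expect_equal(normalize_mirna(counts * 7), normalize_mirna(counts))
  expect_error(normalize_mirna(c(a = 0, b = 0)), "zero")
})

test_that("end heterogeneity: homogeneity score and isoform fractions", {
  construct <- hairpin_seq(build_sairna(probe_site()))
  # all reads identical: homogeneity 1
  rs1 <- preprocess_reads(rep(paste0(substr(construct, 1, 22), ADAPTOR), 8),
                          ADAPTOR)
  het1 <- end_heterogeneity(rs1, construct)
  expect_equal(unname(het1$homogeneity5["5p"]), 1)
  expect_equal(sum(het1$isoforms$fraction), 1)
  # 50/50 split between two 5' starts: homogeneity 0.5
  rs2 <- preprocess_reads(c(rep(paste0(substr(construct, 1, 22), ADAPTOR), 5),
                            rep(paste0(substr(construct, 2, 23), ADAPTOR), 5)),
                          ADAPTOR)
  het2 <- end_heterogeneity(rs2, construct)
  expect_equal(unname(het2$homogeneity5["5p"]), 0.5)
  # per-strand fractions each sum to 1
  rs3 <- preprocess_reads(
    c(rep(paste0(substr(construct, 1, 21), ADAPTOR), 6),
      rep(paste0(substr(construct, 18, 38), ADAPTOR), 4)), ADAPTOR)
  het3 <- end_heterogeneity(rs3, construct)
  for (s in unique(het3$isoforms$strand)) {
    expect_equal(sum(het3$isoforms$fraction[het3$isoforms$strand == s]), 1)
  }
  # unmapped-only input: empty table
  rs4 <- preprocess_reads(paste0(random_rna(21, seed = 66), ADAPTOR), ADAPTOR)
  expect_equal(end_heterogeneity(rs4, construct)$n_mapped, 0L)
})

test_that("synthetic reads reproduce species proportions within 3 sigma", {
  d <- build_sairna(probe_site())
  sim <- simulate_processing(d, "WT")
  depth <- 1e5
  reads <- synth_reads(sim, depth, ADAPTOR, rng_seed = 8)
  reads2 <- synth_reads(sim, depth, ADAPTOR, rng_seed = 8)
  expect_identical(reads, reads2)   # seed reproducibility
  rs <- preprocess_reads(reads, ADAPTOR)
  expect_equal(rs$total_useful, depth)
  # recover per-species proportions from the collapsed unique sequences
  p <- sim$species$weight / sum(sim$species$weight)
  got <- rs$reads$count[match(sim$species$seq, rs$reads$seq)]
  got[is.na(got)] <- 0L
  for (k in seq_along(p)) {
    sigma <- sqrt(depth * p[k] * (1 - p[k]))
    expect_lt(abs(got[k] - depth * p[k]), 3 * sigma + 1e-9,
              label = paste("species", sim$species$species[k]))
  }
  # zero jitter: one isoform per species; with jitter, several 3' isoforms
  # but a fixed 5' end keeps 5' homogeneity at 1
  jit <- synth_reads(sim, 2000, ADAPTOR, jitter5 = 0, jitter3 = 2,
                     rng_seed = 9)
  het <- end_heterogeneity(preprocess_reads(jit, ADAPTOR),
                           hairpin_seq(d))
  expect_equal(unname(het$homogeneity5["5p"]), 1)
  expect_gt(length(unique(het$isoforms$end)), 1L)
  # zero depth: empty output
  expect_equal(nrow(synth_reads(sim, 0)), 0L)
})
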