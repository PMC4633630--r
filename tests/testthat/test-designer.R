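# Hairpin construction rules, site scanning, asymmetry scoring, cloning oligos.

test_that("site scanning matches brute-force enumeration and applies filters", {
  cons <- design_constraints(17, 4)
  # 25-nt input, 21-nt window, no filters: 5 sites at starts 1..5
  mrna <- list(id = "m", seq = random_rna(25, seed = 3))
  sites <- scan_target_sites(mrna, cons, apply_filters = FALSE)
  expect_equal(sites$start, 1:5)
  expect_equal(unique(nchar(sites$window)), 21L)
  # brute-force oracle on a random 200-nt input
  mrna2 <- list(id = "m2", seq = random_rna(200, seed = 4))
  got <- scan_target_sites(mrna2, cons, apply_filters = FALSE)
  expected <- vapply(1:(200 - 21 + 1),
                     function(i) substr(mrna2$seq, i, i + 20), character(1))
  expect_equal(got$window, expected)
  expect_true(all(got$window == substring(mrna2$seq, got$start,
                                          got$start + 20L)))
  # all-G windows fail the GC filter
  mrna3 <- list(id = "m3", seq = strrep("G", 30))
  expect_equal(nrow(scan_target_sites(mrna3, cons)), 0L)
  # shorter than the window: empty with warning
  expect_warning(s <- scan_target_sites(list(id = "s", seq = "ACGUACGU"), cons),
                 "shorter")
  expect_equal(nrow(s), 0L)
})

test_that("guide construction forces a 5' A over the window reverse complement", {
  g <- build_guide(probe_site())
  expect_equal(g$seq, "AGGCAAGCUGACCCUGAAGUU")
  expect_true(g$pos1_forced)
  expect_true(g$pos1_mismatch)  # window ends in G, A cannot pair it
  g2 <- build_guide(list(window = paste0(random_rna(20, seed = 5), "U")))
  expect_false(g2$pos1_mismatch)  # window ends in U: A:U pairs
})

test_that("saiRNA assembly matches the hand-built 17+4 hairpin", {
  d <- build_sairna(probe_site(), 17, 4)
  expect_equal(d$arm5, "AGGCAAGCUGACCCUGA")
  expect_equal(d$loop, "AGUU")
  expect_equal(d$arm3, "UCAGGGUCAGCUUGCCC")  # terminal U -> C mismatch
  expect_equal(hairpin_seq(d), "AGGCAAGCUGACCCUGAAGUUUCAGGGUCAGCUUGCCC")
  expect_equal(nchar(hairpin_seq(d)), 38L)
  expect_equal(d$guide_arm, "FIVE")
  # 18-bp stem on a 22-nt window: 2*18 + 4 = 40 nt core
  d18 <- build_sairna(list(window = random_rna(22, seed = 6)), 18, 4)
  expect_equal(nchar(hairpin_seq(d18)), 40L)
  # A-mismatch variant: terminal residue A, everything else paired
  dA <- build_sairna(probe_site(), 17, 4, mismatch_base = "A")
  expect_equal(substr(dA$arm3, 17, 17), "A")
  expect_equal(substr(dA$arm3, 1, 16), substr(d$arm3, 1, 16))
  expect_error(build_sairna(probe_site(), 21), "16-18")
})

test_that("all non-declared stem positions are Watson-Crick paired", {
  pairs_ok <- function(d) {
    s <- d$stem_len
    for (i in setdiff(seq_len(s), d$mismatches)) {
      a <- substr(d$arm5, i, i)
      b <- substr(d$arm3, s + 1L - i, s + 1L - i)
      if (complement(a, "RNA") != b) return(FALSE)
    }
    TRUE
  }
  for (seed in 1:8) {
    site <- list(window = random_rna(21, seed = seed))
    expect_true(pairs_ok(build_sairna(site)))
    expect_true(pairs_ok(build_shrna_classic(site)))
  }
})

test_that("saiRNA guide positions 2..n are complementary to the window", {
  for (seed in 1:8) {
    w <- random_rna(21, seed = seed + 100)
    d <- build_sairna(list(window = w))
    n <- nchar(w)
    # re-derive the window from the guide: identical except opposite guide 1
    rederived <- revcomp(substr(d$guide, 2, n), "RNA")
    expect_equal(rederived, substr(w, 1, n - 1))
  }
})

test_that("classic shRNA places the pure antisense guide in the 3' arm", {
  d <- build_shrna_classic(probe_site())
  expect_equal(d$arm3, "CGGCAAGCUGACCCUGAAGUU")  # no forced 5' A
  expect_equal(d$arm5, PROBE_WINDOW)
  expect_equal(d$guide_arm, "THREE")
  expect_equal(nchar(hairpin_seq(d)), 2 * 21 + 6)
  expect_equal(length(d$mismatches), 0L)
})

test_that("long-stem 5'-arm shRNA caps complementarity at the window", {
  site <- random_site(21, ctx = 10, seed = 9)
  d <- build_shrna_5arm(site, 22, 4)
  expect_equal(nchar(hairpin_seq(d)), 2 * 22 + 4)
  g <- d$guide
  # positions 2..21 complementary to window 1..20
  expect_equal(substr(g, 2, 21), revcomp(substr(site$window, 1, 20), "RNA"))
  # positions 22..26 copied from downstream context
  expect_equal(substr(g, 22, 26), substr(site$context3, 1, 5))
  expect_equal(substr(d$arm3, 22, 22), "C")
  # 24-bp stem: 52-nt core
  d24 <- build_shrna_5arm(random_site(21, 10, seed = 10), 24, 4)
  expect_equal(nchar(hairpin_seq(d24)), 52L)
  expect_error(build_shrna_5arm(site, 18), "21-24")
})

test_that("asymmetry score: symmetry, sign, swap antisymmetry, re-summation", {
  # palindromic stem pairs with itself: both duplex ends identical
  pal <- "AUGCAUGCAU"  # revcomp(pal) == pal
  expect_equal(revcomp(pal, "RNA"), pal)
  d_pal <- structure(list(arm5 = pal, loop = "GAAA", arm3 = pal,
                          guide = pal, guide_arm = "FIVE",
                          mismatches = integer(0), stem_len = 10L,
                          loop_len = 4L, site = list(window = "x"),
                          loop_complementary = FALSE),
                     class = "hairpin_design")
  expect_equal(asymmetry_score(d_pal), 0)
  # AU-rich guide 5' end vs GC-rich passenger 5' end: negative
  arm5 <- "AUAUCCGGCGGCGCGC"
  d_au <- structure(list(arm5 = arm5, loop = "GAAA",
                         arm3 = revcomp(arm5, "RNA"), guide = arm5,
                         guide_arm = "FIVE", mismatches = integer(0),
                         stem_len = 16L, loop_len = 4L,
                         site = list(window = "x"),
                         loop_complementary = FALSE),
                     class = "hairpin_design")
  expect_lt(asymmetry_score(d_au), 0)
  # strand swap flips the sign
  for (seed in 1:6) {
    d <- build_sairna(list(window = random_rna(21, seed = 200 + seed)))
    swapped <- d
    swapped$guide_arm <- "THREE"
    expect_equal(asymmetry_score(swapped), -asymmetry_score(d))
  }
  # independent re-summation of the embedded table
  d <- build_sairna(probe_site())
  nn <- sairna:::RNA_NN_DG37
  resum <- function(w4, paired) {
    ch <- strsplit(w4, "")[[1]]
    sum(vapply(1:3, function(i) {
      if (paired[i] && paired[i + 1]) nn[[paste0(ch[i], ch[i + 1])]] else 0
    }, numeric(1)))
  }
  # guide 5' window = arm5[1..4] (stem pos 1 is the engineered mismatch);
  # passenger 5' window = arm3[1..4] (stem pos 17..14, all paired)
  expected <- resum(substr(d$arm3, 1, 4), rep(TRUE, 4)) -
    resum(substr(d$arm5, 1, 4), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(asymmetry_score(d), expected, tolerance = 1e-9)
})

test_that("ranking is a stable total order, permutation invariant", {
  designs <- lapply(1:6, function(i) {
    d <- build_sairna(list(window = random_rna(21, seed = 300 + i)))
    d$site$start <- i
    d
  })
  r1 <- rank_candidates(designs)
  expect_equal(nrow(rank_candidates(designs[1])), 1L)
  set.seed(1)
  perm <- sample(6)
  r2 <- rank_candidates(designs[perm])
  expect_equal(r1$total, r2$total)
  expect_equal(r1$start, r2$start)
  expect_equal(r1$total, sort(r1$total))
  # two designs differing only in asymmetry: more negative first
  two <- designs[order(vapply(designs, asymmetry_score, numeric(1)))[c(1, 6)]]
  weights <- c(asymmetry = 1, gc = 0, homopolymer = 0, offtarget = 0)
  r3 <- rank_candidates(two, weights)
  expect_equal(r3$asymmetry, sort(r3$asymmetry))
})

test_that("cloning oligos carry correct sticky ends and reconstruct the insert", {
  d <- build_sairna(probe_site())
  cas <- attach_ribozyme(d, "WT")
  pair <- make_cloning_oligos(cas, "H1_pSilencer")
  expect_true(startsWith(pair$top, "GATCC"))
  expect_true(startsWith(pair$bottom, "AGCTT"))
  # reconstruction oracle: trim the enzyme flanks, complement the bottom
  top_core <- substr(pair$top, 6, nchar(pair$top) - 1)       # GATCC..., ...A
  bot_core <- substr(pair$bottom, 6, nchar(pair$bottom) - 1) # AGCTT..., ...G
  expect_equal(top_core, pair$insert)
  expect_equal(revcomp(bot_core, "DNA"), pair$insert)
  # insert = hairpin + spacer + ribozyme + poly-T terminator
  expect_equal(pair$insert,
               paste0(rna_to_dna(paste0(hairpin_seq(d), "UU",
                                        cas$ribozyme$seq)),
                      strrep("T", 6)))
  # other vectors
  p2 <- make_cloning_oligos(d, "lenti_shRNA")
  expect_true(startsWith(p2$bottom, "CTAGA"))
  p3 <- make_cloning_oligos(d, "lenti_saiRNA_RZ")
  expect_true(endsWith(p3$top, "GCATG"))
  # internal enzyme site detection
  bad <- structure(d, class = "hairpin_design")
  bad$loop <- "GGAUCC"  # BamHI site after DNA conversion
  bad$loop_len <- 6L
  expect_error(make_cloning_oligos(bad, "H1_pSilencer"), "BamHI.*position")
})
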