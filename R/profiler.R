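# Small-RNA-seq profiler: adaptor clipping and length filtering, collapsing
# to unique reads, sequential exact-match categorization against reference
# sets, 5'-anchored miRNA counting, per-million-miRNA normalization, and
# 5'/3' end-heterogeneity tables; plus a synthetic read generator that turns
# simulated species weights into a FASTQ fixture.

#' Preprocess raw small-RNA reads
#'
#' Clips each read at the first occurrence of the 3' adaptor (a full-adaptor
#' match anywhere, or a terminal adaptor prefix of at least `min_adaptor`
#' nt), removes reads that cannot be clipped or whose clipped insert is
#' shorter than `min_len`, and collapses survivors to unique sequences with
#' multiplicities ("useful reads").
#'
#' @param reads Data.frame from [read_fastq()] (columns `id`, `seq`) or a
#'   character vector of read sequences.
#' @param adaptor 3' adaptor sequence (>= 6 nt), same alphabet as the reads.
#' @param min_len Minimum clipped insert length (default 19).
#' @param min_adaptor Minimum terminal adaptor-prefix match (default 6).
#' @return A list of class `read_set`: `reads` (data.frame `seq`, `count`),
#'   `total_raw`, `total_useful`.
#' @export
preprocess_reads <- function(reads, adaptor, min_len = 19L, min_adaptor = 6L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  seqs <- toupper(seqs)
  adaptor <- toupper(adaptor)
  if (nchar(adaptor) < 6L) stop("adaptor must be at least 6 nt")
  total_raw <- length(seqs)
  clip_one <- function(s) {
    pos <- regexpr(adaptor, s, fixed = TRUE)[1]
    if (pos != -1L) return(substr(s, 1L, pos - 1L))
    # adaptor running off the read 3' end: longest terminal adaptor prefix
    kmax <- min(nchar(adaptor) - 1L, nchar(s))
    if (kmax >= min_adaptor) {
      for (k in kmax:min_adaptor) {
        if (substr(s, nchar(s) - k + 1L, nchar(s)) == substr(adaptor, 1L, k)) {
          return(substr(s, 1L, nchar(s) - k))
        }
      }
    }
    NA_character_
  }
  clipped <- vapply(seqs, clip_one, character(1), USE.NAMES = FALSE)
  keep <- !is.na(clipped) & nchar(clipped) >= min_len
  collapsed <- if (!any(keep)) {
    data.frame(seq = character(), count = integer(), stringsAsFactors = FALSE)
  } else {
    tab <- table(clipped[keep])
    data.frame(seq = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  collapsed <- collapsed[order(-collapsed$count, collapsed$seq), , drop = FALSE]
  rownames(collapsed) <- NULL
  structure(list(reads = collapsed, total_raw = total_raw,
                 total_useful = sum(collapsed$count)),
            class = "read_set")
}

#' Annotation bundle for read classification
#'
#' @param mirna Data.frame with columns `name`, `precursor` (precursor
#'   sequence), `mature_start` (1-based 5' start of the mature miRNA within
#'   the precursor), `mature_seq`.
#' @param trna,rrna,snorna,other Character vectors of reference sequences
#'   (may be empty). `other` stands in for the remaining mapped genome.
#' @return A list of class `annotation_set`.
#' @export
annotation_set <- function(mirna = NULL, trna = character(),
                           rrna = character(), snorna = character(),
                           other = character()) {
  if (!is.null(mirna)) {
    stopifnot(all(c("name", "precursor", "mature_start", "mature_seq") %in%
                    names(mirna)))
    ok <- mapply(function(p, st, m) {
      st >= 1L && st + nchar(m) - 1L <= nchar(p) &&
        substr(p, st, st + nchar(m) - 1L) == m
    }, mirna$precursor, mirna$mature_start, mirna$mature_seq)
    if (!all(ok)) {
      stop("mature miRNA coordinates inconsistent with precursor for: ",
           paste(mirna$name[!ok], collapse = ", "))
    }
  }
  structure(list(mirna = mirna, trna = trna, rrna = rrna, snorna = snorna,
                 other = other),
            class = "annotation_set")
}

# TRUE if `read` matches (exact substring, either strand) any sequence in refs.
matches_any <- function(read, refs) {
  if (length(refs) == 0L) return(FALSE)
  rc <- revcomp(read)
  any(vapply(refs, function(r) {
    grepl(read, r, fixed = TRUE) || grepl(rc, r, fixed = TRUE)
  }, logical(1)))
}

#' Sequentially categorize useful reads
#'
#' Assigns each unique read to the first matching class, in order:
#' silencing construct, miRNA (precursor sequences), tRNA, rRNA, snoRNA,
#' other reference, unmapped. Matching is exact substring with no mismatches,
#' on either strand of the reference; counts are weighted by read
#' multiplicity, so the categories are disjoint and sum to the useful total.
#'
#' @param readset A `read_set` from [preprocess_reads()].
#' @param annotations An [annotation_set()].
#' @param construct Construct (hairpin) sequence(s), e.g.
#'   `hairpin_seq(design)`; may be empty.
#' @return A list of class `category_counts`: named integer vector `counts`
#'   (classes `construct`, `mirna`, `trna`, `rrna`, `snorna`, `other`,
#'   `unmapped`), `total_useful`, per-read class assignments in `assignment`.
#' @export
classify_reads <- function(readset, annotations, construct = character()) {
  stopifnot(inherits(readset, "read_set"),
            inherits(annotations, "annotation_set"))
  refs <- list(
    construct = as.character(construct),
    mirna = if (is.null(annotations$mirna)) character() else
      annotations$mirna$precursor,
    trna = annotations$trna, rrna = annotations$rrna,
    snorna = annotations$snorna, other = annotations$other)
  if (all(lengths(refs) == 0L)) {
    warning("all reference sets are empty; every read is unmapped")
  }
  classes <- c(names(refs), "unmapped")
  assign_one <- function(read) {
    for (cl in names(refs)) {
      if (matches_any(read, refs[[cl]])) return(cl)
    }
    "unmapped"
  }
  assigned <- vapply(readset$reads$seq, assign_one, character(1),
                     USE.NAMES = FALSE)
  counts <- vapply(classes, function(cl) {
    sum(readset$reads$count[assigned == cl])
  }, integer(1))
  structure(list(counts = counts, total_useful = readset$total_useful,
                 assignment = data.frame(seq = readset$reads$seq,
                                         count = readset$reads$count,
                                         class = assigned,
                                         stringsAsFactors = FALSE)),
            class = "category_counts")
}

#' 5'-anchored mature miRNA counting
#'
#' A read counts toward a miRNA only if its 5' end coincides exactly with the
#' annotated mature 5' start on the precursor and its 3' end lies within 2 nt
#' of the mature 3' end; 3' additions must be templated by the precursor
#' (the read must match the precursor from the mature start over its full
#' length).
#'
#' @param readset A `read_set`.
#' @param annotations An [annotation_set()] with a miRNA table.
#' @return Named integer vector of per-miRNA counts.
#' @export
count_mirna <- function(readset, annotations) {
  stopifnot(inherits(readset, "read_set"))
  mi <- annotations$mirna
  if (is.null(mi) || nrow(mi) == 0L) stop("no miRNA annotation provided")
  counts <- stats::setNames(integer(nrow(mi)), mi$name)
  for (k in seq_len(nrow(mi))) {
    st <- mi$mature_start[k]
    mlen <- nchar(mi$mature_seq[k])
    for (r in seq_len(nrow(readset$reads))) {
      read <- readset$reads$seq[r]
      rl <- nchar(read)
      if (rl < mlen - 2L || rl > mlen + 2L) next
      if (st + rl - 1L > nchar(mi$precursor[k])) next
      if (substr(mi$precursor[k], st, st + rl - 1L) == read) {
        counts[k] <- counts[k] + readset$reads$count[r]
      }
    }
  }
  counts
}

#' Per-million-miRNA normalization
#'
#' Each count is divided by the total miRNA count and multiplied by
#' 1,000,000; values keep full precision, so they sum to exactly 1e6.
#'
#' @param counts Named numeric vector of miRNA counts (sum > 0).
#' @return Named numeric vector of normalized abundances.
#' @export
normalize_mirna <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("total miRNA count is zero; cannot normalize")
  counts / total * 1e6
}

#' Isoform (end-heterogeneity) table for a construct
#'
#' Maps each unique read exactly into the construct sequence (first match),
#' tabulates (5' position, 3' position) isoforms with per-strand fractions,
#' and reports per strand the two most abundant isoforms and a 5'-homogeneity
#' score — the fraction of that strand's reads sharing the modal 5' position.
#' Reads are assigned to the 5'-arm or 3'-arm strand by the midpoint of their
#' mapped footprint relative to the construct midpoint.
#'
#' @param readset A `read_set`.
#' @param construct The construct (hairpin precursor) sequence.
#' @return A list of class `isoform_table`: `isoforms` (data.frame `strand`,
#'   `start`, `end`, `count`, `fraction`), `top2` (best two isoforms per
#'   strand), `homogeneity5` (named per-strand scores), `n_mapped`.
#' @export
end_heterogeneity <- function(readset, construct) {
  stopifnot(inherits(readset, "read_set"))
  construct <- dna_to_rna(toupper(construct))
  mid <- nchar(construct) / 2
  rows <- list()
  for (r in seq_len(nrow(readset$reads))) {
    read <- readset$reads$seq[r]
    pos <- regexpr(read, construct, fixed = TRUE)[1]
    if (pos == -1L) next
    end <- pos + nchar(read) - 1L
    strand <- if ((pos + end) / 2 <= mid) "5p" else "3p"
    rows[[length(rows) + 1L]] <- data.frame(
      strand = strand, start = pos, end = end,
      count = readset$reads$count[r], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    iso <- data.frame(strand = character(), start = integer(),
                      end = integer(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE)
    return(structure(list(isoforms = iso, top2 = iso,
                          homogeneity5 = numeric(0), n_mapped = 0L),
                     class = "isoform_table"))
  }
  iso <- do.call(rbind, rows)
  iso <- stats::aggregate(count ~ strand + start + end, data = iso, sum)
  strand_tot <- tapply(iso$count, iso$strand, sum)
  iso$fraction <- iso$count / as.numeric(strand_tot[iso$strand])
  iso <- iso[order(iso$strand, -iso$count), , drop = FALSE]
  rownames(iso) <- NULL
  top2 <- do.call(rbind, lapply(split(iso, iso$strand), utils::head, 2L))
  rownames(top2) <- NULL
  homog <- vapply(split(iso, iso$strand), function(s) {
    by5 <- tapply(s$count, s$start, sum)
    max(by5) / sum(by5)
  }, numeric(1))
  structure(list(isoforms = iso, top2 = top2, homogeneity5 = homog,
                 n_mapped = sum(iso$count)),
            class = "isoform_table")
}

#' Generate a synthetic small-RNA FASTQ from a processing outcome
#'
#' Samples reads in proportion to the simulated species weights, applies
#' optional uniform 5'/3' end jitter, appends the 3' adaptor, and writes a
#' FASTQ file. Fully reproducible given the seed; at depth 1e5 the recovered
#' species proportions match the weights within binomial error.
#'
#' @param outcome A `processing_outcome` (or any data.frame with `species`,
#'   `seq`, `weight`).
#' @param depth Number of reads to draw.
#' @param adaptor 3' adaptor appended to each read (default a standard
#'   small-RNA adaptor prefix).
#' @param jitter5,jitter3 Maximum uniform end jitter in nt (default 0; 5'
#'   jitter trims the read 5' end, 3' jitter trims the 3' end).
#' @param rng_seed Integer seed.
#' @param path Output FASTQ path (`.gz` allowed); `NULL` returns the read
#'   data.frame without writing.
#' @return Invisibly, the read data.frame (`id`, `seq`, `species`).
#' @export
synth_reads <- function(outcome, depth, adaptor = "UCGUAUGCCGUCUUCUGCUUGU",
                        jitter5 = 0L, jitter3 = 0L, rng_seed = 1L,
                        path = NULL) {
  species <- if (inherits(outcome, "processing_outcome")) outcome$species
             else outcome
  stopifnot(all(c("species", "seq", "weight") %in% names(species)))
  if (nrow(species) == 0L) stop("outcome has no species")
  if (depth == 0L) {
    reads <- data.frame(id = character(), seq = character(),
                        species = character(), stringsAsFactors = FALSE)
    if (!is.null(path)) write_fastq(reads, path)
    return(invisible(reads))
  }
  set.seed(rng_seed)
  pick <- sample(nrow(species), depth, replace = TRUE,
                 prob = species$weight / sum(species$weight))
  seqs <- species$seq[pick]
  if (jitter5 > 0L || jitter3 > 0L) {
    j5 <- sample(0:jitter5, depth, replace = TRUE)
    j3 <- sample(0:jitter3, depth, replace = TRUE)
    seqs <- substr(seqs, 1L + j5, nchar(seqs) - j3)
  }
  reads <- data.frame(id = sprintf("read%06d", seq_len(depth)),
                      seq = paste0(seqs, toupper(adaptor)),
                      species = species$species[pick],
                      stringsAsFactors = FALSE)
  if (!is.null(path)) write_fastq(reads, path)
  invisible(reads)
}
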