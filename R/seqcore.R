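# Sequence primitives shared by all modules. Sequences are plain uppercase
# character scalars, always written 5'->3'; the alphabet ("DNA" or "RNA") is
# carried explicitly by the functions that need it. Coordinates are 1-based
# and inclusive throughout the package.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

#' Validate a nucleotide sequence
#'
#' Checks that every residue belongs to the declared alphabet and returns the
#' uppercased sequence. IUPAC ambiguity codes are rejected unless
#' `permissive = TRUE`, in which case they are tolerated but callers are
#' expected to exclude them from design windows.
#'
#' @param seq Character scalar, the sequence (5'->3').
#' @param alphabet `"DNA"`, `"RNA"`, or `"auto"` (infer from T/U content;
#'   sequences containing neither default to RNA).
#' @param permissive Logical; allow IUPAC ambiguity codes.
#' @return The validated, uppercased sequence (a plain character scalar).
#' @export
validate_nucseq <- function(seq, alphabet = "auto", permissive = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("sequence must have length >= 1")
  alphabet <- resolve_alphabet(seq, alphabet)
  bases <- if (alphabet == "DNA") DNA_BASES else RNA_BASES
  allowed <- if (permissive) c(bases, strsplit("RYSWKMBDHVN", "")[[1]]) else bases
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s residue '%s' at position %d", alphabet,
                 chars[bad[1]], bad[1]))
  }
  unname(seq)
}

resolve_alphabet <- function(seq, alphabet) {
  if (alphabet %in% c("DNA", "RNA")) return(alphabet)
  if (!identical(alphabet, "auto")) stop("alphabet must be 'DNA', 'RNA' or 'auto'")
  has_t <- grepl("T", seq, fixed = TRUE)
  has_u <- grepl("U", seq, fixed = TRUE)
  if (has_t && has_u) stop("sequence mixes T and U; declare the alphabet explicitly")
  if (has_t) "DNA" else "RNA"
}

#' Reverse complement
#'
#' Length-preserving involution in the sequence's own alphabet.
#'
#' @inheritParams validate_nucseq
#' @return Character scalar, the reverse complement (5'->3').
#' @examples
#' revcomp("AACUUCAGGGUCAGCUUGCCG")  # "CGGCAAGCUGACCCUGAAGUU"
#' @export
revcomp <- function(seq, alphabet = "auto") {
  seq <- validate_nucseq(seq, alphabet)
  paste(rev(strsplit(complement(seq, alphabet), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Complement (same orientation)
#' @inheritParams validate_nucseq
#' @export
complement <- function(seq, alphabet = "auto") {
  seq <- validate_nucseq(seq, alphabet)
  if (resolve_alphabet(seq, alphabet) == "DNA") chartr("ACGT", "TGCA", seq)
  else chartr("ACGU", "UGCA", seq)
}

#' Convert between DNA and RNA alphabets
#'
#' T and U are interconverted; the conversion is an involution and preserves
#' length. Designs are reported in RNA, cloning oligos in DNA.
#' @param seq Character scalar.
#' @export
dna_to_rna <- function(seq) chartr("Tt", "Uu", toupper(seq))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(seq) chartr("Uu", "Tt", toupper(seq))

#' GC fraction of a sequence
#' @param seq Character scalar.
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

# Longest homopolymer run of `base` in seq (0 if absent).
max_run <- function(seq, base) {
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  runs <- r$lengths[r$values == base]
  if (length(runs) == 0L) 0L else max(runs)
}

# Longest homopolymer run of any base.
max_homopolymer <- function(seq) {
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  max(r$lengths)
}

#' End chemistry descriptor
#'
#' Records the chemical state of both termini of an RNA molecule. Ribozyme
#' self-cleavage leaves a 2',3'-cyclic phosphate on the upstream product;
#' T4 PNK (without ATP) converts it to a hydroxyl.
#'
#' @param five_prime One of `"PPP"`, `"P"`, `"OH"`.
#' @param three_prime One of `"OH"`, `"CyclicP"`, `"P"`.
#' @return A named list of class `end_chemistry`.
#' @export
end_chemistry <- function(five_prime = "PPP", three_prime = "OH") {
  five_prime <- match.arg(five_prime, c("PPP", "P", "OH"))
  three_prime <- match.arg(three_prime, c("OH", "CyclicP", "P"))
  structure(list(five_prime = five_prime, three_prime = three_prime),
            class = "end_chemistry")
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()]. Lowercase input is uppercased with a
#' one-time warning per file; duplicate record ids are an error.
#'
#' @param path Path to a FASTA file (line-wrapped or single-line).
#' @param alphabet Alphabet to validate against (`"auto"` infers per record).
#' @param strict Reject IUPAC ambiguity codes (default `TRUE`).
#' @return A data.frame with columns `id`, `description`, `seq`.
#' @export
read_fasta <- function(path, alphabet = "auto", strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) {
    return(data.frame(id = character(), description = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues in ", path, " uppercased on read")
    seqs <- toupper(seqs)
  }
  for (i in seq_along(seqs)) {
    validate_nucseq(seqs[i], alphabet, permissive = !strict)
  }
  data.frame(id = ids, description = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records Data.frame with columns `id`, `seq` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate ids in records")
  set <- Biostrings::BStringSet(records$seq)
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read a 4-line-dialect FASTQ file
#'
#' Strict 4-line records (no wrapping). Gzip-compressed files are handled
#' transparently. Qualities are carried but unused downstream.
#'
#' @param path Path to a FASTQ file, optionally gzipped.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)  # readLines decompresses gzip transparently
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record starting at line %d", (n %/% 4L) * 4L + 1L))
  }
  first <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad_hdr <- which(!startsWith(first, "@"))
  if (length(bad_hdr) > 0L) {
    stop(sprintf("FASTQ parse error at line %d: header must start with '@'",
                 (bad_hdr[1] - 1L) * 4L + 1L))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0L) {
    stop(sprintf("FASTQ parse error at line %d: separator must start with '+'",
                 (bad_plus[1] - 1L) * 4L + 3L))
  }
  bad_q <- which(nchar(quals) != nchar(seqs))
  if (length(bad_q) > 0L) {
    stop(sprintf("FASTQ parse error at line %d: quality length %d != sequence length %d",
                 (bad_q[1] - 1L) * 4L + 4L, nchar(quals[bad_q[1]]), nchar(seqs[bad_q[1]])))
  }
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues in ", path, " uppercased on read")
    seqs <- toupper(seqs)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", first)),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#' @param reads Data.frame with columns `id`, `seq` and optionally `qual`
#'   (defaults to maximal quality `"I"` per base).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)), con)
  }
  invisible(path)
}
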