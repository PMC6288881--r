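# Genome preparation: the four three-letter reference transformations and
# their exact k-mer seed indexes.

CONVERSION_TAGS <- c("W-CT", "W-GA", "C-CT", "C-GA")

#' Normalize a nucleotide sequence
#'
#' Uppercases the sequence and maps any IUPAC ambiguity code other than N to N
#' (with a warning). Characters that are not IUPAC nucleotide codes at all are
#' rejected.
#'
#' @param seq Character scalar.
#' @return Normalized sequence over \{A,C,G,T,N\}.
#' @keywords internal
normalize_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    bad <- regmatches(s, gregexpr("[^ACGTN]", s))[[1]]
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
    if (!all(bad %in% iupac)) {
      pos <- regexpr(sprintf("[^ACGTN%s]", paste(iupac, collapse = "")), s)
      stop(sprintf("invalid nucleotide '%s' at position %d",
                   substr(s, pos, pos), pos))
    }
    warning(sprintf("mapped %d IUPAC ambiguity base(s) to N", length(bad)))
    s <- gsub(sprintf("[%s]", paste(iupac, collapse = "")), "N", s)
  }
  s
}

.check_alphabet <- function(seq) {
  pos <- regexpr("[^ACGTN]", seq)
  if (pos > 0L)
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(seq, pos, pos), pos))
  invisible(TRUE)
}

#' Construct a reference genome object
#'
#' @param sequences Named character vector of nucleotide sequences. Names must
#'   be unique, sequences non-empty; lowercase is uppercased and IUPAC
#'   ambiguity codes other than N become N.
#' @return A `ReferenceGenome`: list with `sequences` (named character) and
#'   `lengths` (named integer).
#' @export
reference_genome <- function(sequences) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("sequence names must be unique")
  if (any(nchar(sequences) == 0L))
    stop("sequences must be non-empty")
  seqs <- vapply(sequences, normalize_sequence, character(1))
  structure(
    list(sequences = seqs, lengths = setNames(nchar(seqs), names(seqs))),
    class = "ReferenceGenome"
  )
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat(sprintf("ReferenceGenome: %d sequence(s), %s bases total\n",
              length(x$sequences), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (multi-sequence, wrapped or unwrapped).
#' @return A `ReferenceGenome`.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop(sprintf("no sequences in FASTA: %s", path))
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))  # id up to first whitespace
  reference_genome(seqs)
}

#' Convert a sequence to its three-letter form
#'
#' CT conversion replaces every C with T; GA replaces every G with A. All
#' other characters (including N) are unchanged and length is preserved.
#'
#' @param seq Uppercase sequence over \{A,C,G,T,N\}.
#' @param rule `"CT"` or `"GA"`.
#' @return Converted sequence.
#' @export
convert_sequence <- function(seq, rule = c("CT", "GA")) {
  rule <- match.arg(rule)
  .check_alphabet(seq)
  if (rule == "CT") chartr("C", "T", seq) else chartr("G", "A", seq)
}

#' Reverse complement
#'
#' @param seq Uppercase sequence over \{A,C,G,T,N\}; N complements to N.
#' @return Reverse complement.
#' @export
reverse_complement <- function(seq) {
  .check_alphabet(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  intToUtf8(rev(utf8ToInt(comp)))
}

#' Build the four converted genomes
#'
#' Produces W-CT = CT(Watson), W-GA = GA(Watson), C-CT = CT(revcomp(Watson)),
#' C-GA = GA(revcomp(Watson)), applied per sequence. Crick genomes are stored
#' in Crick orientation; coordinate lift-over to Watson happens in the
#' resolver.
#'
#' @param ref A `ReferenceGenome`.
#' @return Named list of four `ConvertedGenome` objects
#'   (`W-CT`, `W-GA`, `C-CT`, `C-GA`).
#' @export
make_converted_genomes <- function(ref) {
  stopifnot(inherits(ref, "ReferenceGenome"))
  watson <- ref$sequences
  crick <- vapply(watson, reverse_complement, character(1))
  build <- function(tag, seqs) {
    structure(
      list(tag = tag, sequences = seqs, source_lengths = ref$lengths),
      class = "ConvertedGenome"
    )
  }
  list(
    "W-CT" = build("W-CT", vapply(watson, convert_sequence, character(1), rule = "CT")),
    "W-GA" = build("W-GA", vapply(watson, convert_sequence, character(1), rule = "GA")),
    "C-CT" = build("C-CT", vapply(crick, convert_sequence, character(1), rule = "CT")),
    "C-GA" = build("C-GA", vapply(crick, convert_sequence, character(1), rule = "GA"))
  )
}

#' @export
print.ConvertedGenome <- function(x, ...) {
  cat(sprintf("ConvertedGenome [%s]: %d sequence(s)\n", x$tag,
              length(x$sequences)))
  invisible(x)
}

#' Build an exact k-mer seed index over a converted genome
#'
#' Indexes every N-free k-mer of each sequence with its 0-based start
#' positions. Backed by a compiled hash table; query through [seed_lookup()].
#'
#' @param genome A `ConvertedGenome` (or named character vector of sequences).
#' @param k Seed length, `1 <= k <= min(sequence length)` and at most 31.
#' @return A `seed_index` object.
#' @export
build_seed_index <- function(genome, k = 20L) {
  seqs <- if (inherits(genome, "ConvertedGenome")) genome$sequences else genome
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  k <- as.integer(k)
  if (k < 1L || k > min(nchar(seqs)))
    stop(sprintf("seed length k=%d out of range [1, %d]", k, min(nchar(seqs))))
  if (k > 31L) stop("seed length k must be <= 31")
  structure(
    list(
      k = k,
      ptr = cpp_seed_index_build(unname(seqs), k),
      seq_names = names(seqs),
      seq_lengths = setNames(nchar(seqs), names(seqs)),
      tag = if (inherits(genome, "ConvertedGenome")) genome$tag else NA_character_
    ),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: k=%d, %d sequence(s), %d distinct k-mers\n",
              x$k, length(x$seq_names), cpp_seed_index_nkmers(x$ptr)))
  invisible(x)
}

#' Query a seed index for one k-mer
#'
#' @param index A `seed_index`.
#' @param kmer Query of length `k`; k-mers containing N return no positions.
#' @return data.frame with `seq_name` and 0-based `pos`, sorted.
#' @export
seed_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"))
  hits <- cpp_seed_lookup(index$ptr, kmer)
  out <- data.frame(
    seq_name = index$seq_names[hits$seq],
    pos = hits$pos,
    stringsAsFactors = FALSE
  )
  out[order(match(out$seq_name, index$seq_names), out$pos), , drop = FALSE]
}

#' Prepare a genome pack
#'
#' Builds the four converted genomes and their seed indexes from a reference.
#'
#' @param ref A `ReferenceGenome` or path to a FASTA file.
#' @param k Seed length (default 20).
#' @return A `genome_pack`: list with `ref`, `genomes` (four
#'   `ConvertedGenome`s), `indexes` (four `seed_index`es), `k`, `source_md5`.
#' @export
prepare_genome <- function(ref, k = 20L) {
  source_md5 <- NA_character_
  if (is.character(ref) && length(ref) == 1L) {
    source_md5 <- unname(tools::md5sum(ref))
    ref <- read_reference_fasta(ref)
  }
  stopifnot(inherits(ref, "ReferenceGenome"))
  genomes <- make_converted_genomes(ref)
  indexes <- lapply(genomes, build_seed_index, k = k)
  structure(
    list(ref = ref, genomes = genomes, indexes = indexes, k = as.integer(k),
         source_md5 = source_md5),
    class = "genome_pack"
  )
}

#' @export
print.genome_pack <- function(x, ...) {
  cat(sprintf("genome_pack: k=%d, %d sequence(s), tags: %s\n", x$k,
              length(x$ref$sequences), paste(names(x$genomes), collapse = " ")))
  invisible(x)
}

.write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
}

PACK_FORMAT_VERSION <- 1L

#' Save a genome pack to a directory
#'
#' Layout: `original.fa` plus one converted FASTA per tag (`W-CT.fa`, ...)
#' and `metadata.json` (format version, k, source checksum, sequence names
#' and lengths). Seed indexes are rebuilt deterministically at load time
#' rather than serialized.
#'
#' @param pack A `genome_pack`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_genome_pack <- function(pack, dir) {
  stopifnot(inherits(pack, "genome_pack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_fasta(pack$ref$sequences, file.path(dir, "original.fa"))
  for (tag in CONVERSION_TAGS)
    .write_fasta(pack$genomes[[tag]]$sequences,
                 file.path(dir, paste0(tag, ".fa")))
  source_md5 <- pack$source_md5
  if (is.na(source_md5))
    source_md5 <- unname(tools::md5sum(file.path(dir, "original.fa")))
  meta <- list(
    format_version = PACK_FORMAT_VERSION,
    k = pack$k,
    source_md5 = source_md5,
    seq_names = names(pack$ref$sequences),
    seq_lengths = unname(pack$ref$lengths)
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a genome pack from a directory
#'
#' Verifies that every component is present, rebuilds the seed indexes, and
#' optionally checks the pack against a source FASTA checksum (mismatch is a
#' warning, not an error).
#'
#' @param dir Pack directory written by [save_genome_pack()].
#' @param fasta Optional path to the source FASTA to verify against.
#' @return A `genome_pack`.
#' @export
load_genome_pack <- function(dir, fasta = NULL) {
  if (!dir.exists(dir)) stop(sprintf("genome pack directory not found: %s", dir))
  needed <- c("metadata.json", "original.fa", paste0(CONVERSION_TAGS, ".fa"))
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing))
    stop(sprintf("genome pack is missing component(s): %s",
                 paste(missing, collapse = ", ")))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version > PACK_FORMAT_VERSION)
    stop("unsupported genome pack format version")
  ref <- read_reference_fasta(file.path(dir, "original.fa"))
  if (!identical(names(ref$sequences), meta$seq_names))
    stop("genome pack corrupt: sequence names do not match metadata")
  genomes <- list()
  for (tag in CONVERSION_TAGS) {
    seqs <- read_reference_fasta(file.path(dir, paste0(tag, ".fa")))$sequences
    if (!identical(unname(nchar(seqs)), unname(nchar(ref$sequences))))
      stop(sprintf("genome pack corrupt: %s.fa lengths do not match source", tag))
    genomes[[tag]] <- structure(
      list(tag = tag, sequences = seqs, source_lengths = ref$lengths),
      class = "ConvertedGenome"
    )
  }
  if (!is.null(fasta)) {
    md5 <- unname(tools::md5sum(fasta))
    if (!is.na(meta$source_md5) && !identical(md5, meta$source_md5))
      warning(sprintf(
        "checksum of %s does not match the checksum recorded in the pack", fasta))
  }
  indexes <- lapply(genomes, build_seed_index, k = as.integer(meta$k))
  structure(
    list(ref = ref, genomes = genomes, indexes = indexes,
         k = as.integer(meta$k), source_md5 = meta$source_md5),
    class = "genome_pack"
  )
}
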